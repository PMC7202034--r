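# KA/KS between pairs of codon-aligned coding sequences, via degeneracy
# site classes (L0/L2/L4) and per-class Kimura two-parameter corrections.

SATURATION_VALUE <- 9.999999

#' Site-class counts and observed substitution proportions for a codon pair
#'
#' Walks the both-ungapped codon columns of two aligned rows. Each nucleotide
#' position is classified (nondegenerate / twofold / fourfold) against each
#' sequence's own codon, and the class tallies `L0`, `L2`, `L4` are averaged
#' over the two sequences (so they may be fractional). Each differing
#' nucleotide is recorded as a transition (A-G, C-T) or transversion, with
#' half a count at the site class of each sequence; multi-hit codons are
#' decomposed position-wise.
#'
#' @param s1,s2 Aligned codon strings (equal length, gap `-`).
#' @return List with `L` (`L0`,`L2`,`L4`), transition counts `ts`,
#'   transversion counts `tv`, proportions `P` and `Q` per class, and
#'   `codons_compared`.
#' @export
count_sites_and_substitutions <- function(s1, s2) {
  if (nchar(s1) != nchar(s2))
    stop("aligned rows must have equal length", call. = FALSE)
  c1 <- split_codons(s1)
  c2 <- split_codons(s2)
  deg <- degeneracy_table()
  valid <- rownames(deg)
  L <- c(`0` = 0, `2` = 0, `4` = 0)
  ts <- tv <- c(`0` = 0, `2` = 0, `4` = 0)
  ncomp <- 0L
  for (i in seq_along(c1)) {
    a <- c1[i]; b <- c2[i]
    if (!(a %in% valid) || !(b %in% valid)) next  # gap / ambiguity / stop
    ncomp <- ncomp + 1L
    da <- deg[a, ]; db <- deg[b, ]
    for (p in 1:3) {
      ka <- as.character(da[p]); kb <- as.character(db[p])
      L[ka] <- L[ka] + 0.5
      L[kb] <- L[kb] + 0.5
      x <- substring(a, p, p); y <- substring(b, p, p)
      if (x != y) {
        if (is_transition(x, y)) {
          ts[ka] <- ts[ka] + 0.5; ts[kb] <- ts[kb] + 0.5
        } else {
          tv[ka] <- tv[ka] + 0.5; tv[kb] <- tv[kb] + 0.5
        }
      }
    }
  }
  if (ncomp == 0L)
    stop("empty-overlap: no comparable codon columns", call. = FALSE)
  P <- ifelse(L > 0, ts / L, 0)
  Q <- ifelse(L > 0, tv / L, 0)
  nm <- c("L0", "L2", "L4")
  list(L = stats::setNames(as.numeric(L), nm),
       ts = stats::setNames(as.numeric(ts), nm),
       tv = stats::setNames(as.numeric(tv), nm),
       P = stats::setNames(as.numeric(P), nm),
       Q = stats::setNames(as.numeric(Q), nm),
       codons_compared = ncomp)
}

#' Kimura two-parameter distance components per degeneracy class
#'
#' For each site class i, the corrected transition component
#' `A_i = 1/2 log(1 / (1 - 2P_i - Q_i)) - 1/4 log(1 / (1 - 2Q_i))` and
#' transversion component `B_i = 1/2 log(1 / (1 - 2Q_i))`. A class is flagged
#' saturated when a log argument is non-positive. Classes with `L_i = 0`
#' contribute zero weight downstream and are not an error.
#'
#' @param P,Q Observed transition / transversion proportions per class
#'   (length-3 vectors, classes 0/2/4).
#' @param L Site counts per class.
#' @return List with `A`, `B` (length-3, possibly `NA` when saturated) and
#'   logical `saturated` per class.
#' @export
correct_distances <- function(P, Q, L = c(1, 1, 1)) {
  stopifnot(length(P) == 3, length(Q) == 3)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  saturated <- (w1 <= 0 | w2 <= 0) & L > 0
  A <- B <- rep(NA_real_, 3)
  oka <- w1 > 0 & w2 > 0
  A[oka] <- 0.5 * log(1 / w1[oka]) - 0.25 * log(1 / w2[oka])
  okb <- w2 > 0
  B[okb] <- 0.5 * log(1 / w2[okb])
  A[L == 0] <- 0
  B[L == 0] <- 0
  nm <- c("A0_B0", "A2_B2", "A4_B4")
  list(A = stats::setNames(A, c("A0", "A2", "A4")),
       B = stats::setNames(B, c("B0", "B2", "B4")),
       saturated = stats::setNames(as.logical(saturated), c("c0", "c2", "c4")))
}

#' Nonsynonymous and synonymous substitution rates for a codon pair
#'
#' Combines the per-class Kimura components into
#' `KA = A0 + (L0 B0 + L2 B2) / (L0 + L2)` and
#' `KS = (L2 A2 + L4 A4) / (L2 + L4) + B4`: transitions at twofold sites are
#' mostly synonymous and so are weighted into KS, while transversions at
#' nondegenerate and twofold sites feed KA. A saturated KA or KS is coerced to
#' 9.999999 and flagged.
#'
#' @param s1,s2 Aligned codon strings from one codon alignment.
#' @param saturation_value Replacement value for saturated estimates.
#' @return A `kaks_result` list: `ka`, `ks`, `ratio` (`NA` when `KS` is 0 or
#'   either side is saturated), `saturated_ka`, `saturated_ks`,
#'   `site_counts`, `components`.
#' @export
ka_ks <- function(s1, s2, saturation_value = SATURATION_VALUE) {
  cnt <- count_sites_and_substitutions(s1, s2)
  comp <- correct_distances(cnt$P, cnt$Q, cnt$L)
  L <- cnt$L; A <- comp$A; B <- comp$B; sat <- comp$saturated
  sat_ka <- isTRUE(sat[1]) || (L[2] > 0 && isTRUE(sat[2]))
  sat_ks <- (L[2] > 0 && isTRUE(sat[2])) || isTRUE(sat[3])
  ka <- if (sat_ka) saturation_value else {
    b_part <- if (L[1] + L[2] > 0)
      (L[1] * B[1] + L[2] * B[2]) / (L[1] + L[2]) else 0
    unname(A[1] + b_part)
  }
  ks <- if (sat_ks) saturation_value else {
    a_part <- if (L[2] + L[3] > 0)
      (L[2] * A[2] + L[3] * A[3]) / (L[2] + L[3]) else 0
    unname(a_part + B[3])
  }
  ratio <- if (!sat_ka && !sat_ks && ks > 0) ka / ks else NA_real_
  structure(list(ka = ka, ks = ks, ratio = ratio,
                 saturated_ka = sat_ka, saturated_ks = sat_ks,
                 site_counts = L, components = comp),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("KA = %.6f%s  KS = %.6f%s  KA/KS = %s\n",
              x$ka, if (x$saturated_ka) " (saturated)" else "",
              x$ks, if (x$saturated_ks) " (saturated)" else "",
              if (is.na(x$ratio)) "NA" else sprintf("%.4f", x$ratio)))
  cat("sites L0/L2/L4:", paste(format(x$site_counts, digits = 4),
                               collapse = " / "), "\n")
  invisible(x)
}

#' All pairwise KA/KS results for a codon alignment
#'
#' @param aln Codon alignment (named character vector, e.g. from
#'   [thread_codon_alignment()]).
#' @param saturation_value Passed to [ka_ks()].
#' @return List with `pairs` (data frame: seq1, seq2, ka, ks, ratio,
#'   saturated_ka, saturated_ks) and symmetric matrices `KA`, `KS`, `ratio`
#'   (zero diagonal).
#' @export
pairwise_kaks_matrix <- function(aln, saturation_value = SATURATION_VALUE) {
  ids <- names(aln)
  n <- length(ids)
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)
  KA <- KS <- RT <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(RT) <- 0
  rows <- list()
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    r <- ka_ks(aln[[i]], aln[[j]], saturation_value)
    KA[i, j] <- KA[j, i] <- r$ka
    KS[i, j] <- KS[j, i] <- r$ks
    RT[i, j] <- RT[j, i] <- if (is.na(r$ratio)) NA_real_ else r$ratio
    rows[[length(rows) + 1L]] <-
      data.frame(seq1 = ids[i], seq2 = ids[j], ka = r$ka, ks = r$ks,
                 ratio = r$ratio, saturated_ka = r$saturated_ka,
                 saturated_ks = r$saturated_ks, stringsAsFactors = FALSE)
  }
  list(pairs = do.call(rbind, rows), KA = KA, KS = KS, ratio = RT)
}

#' Mean KA/KS ratio over all pairs involving a focal sequence
#'
#' @param pairs Pairs data frame from [pairwise_kaks_matrix()]
#'   (or the full list).
#' @param focal Focal sequence id.
#' @param exclude_saturated Drop saturated or undefined ratios (default).
#' @return Arithmetic mean ratio over retained pairs.
#' @export
species_mean_kaks <- function(pairs, focal, exclude_saturated = TRUE) {
  if (is.list(pairs) && !is.data.frame(pairs)) pairs <- pairs$pairs
  sel <- pairs$seq1 == focal | pairs$seq2 == focal
  sub <- pairs[sel, , drop = FALSE]
  if (exclude_saturated)
    sub <- sub[!sub$saturated_ka & !sub$saturated_ks & !is.na(sub$ratio), ,
               drop = FALSE]
  if (nrow(sub) == 0L)
    stop("empty-average: no retained pairs for '", focal, "'", call. = FALSE)
  mean(sub$ratio)
}
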