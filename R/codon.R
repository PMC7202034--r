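# Codon-level helpers: standard genetic code, degeneracy classes, and
# protein-guided threading of coding sequences onto a protein alignment.

genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

NUCS <- c("A", "C", "G", "T")

is_transition <- function(x, y) {
  (x == "A" & y == "G") | (x == "G" & y == "A") |
  (x == "C" & y == "T") | (x == "T" & y == "C")
}

#' Degeneracy class of one codon position
#'
#' Classifies a position of a sense codon by how many of the three possible
#' single-nucleotide changes at that position are synonymous under the
#' standard genetic code: all 3 synonymous gives a fourfold site, at least one
#' (but not all) a twofold site (threefold sites, e.g. Ile position 3, are
#' conventionally classed as twofold), none a nondegenerate site. Changes that
#' create a stop codon are not counted as synonymous.
#'
#' @param codon Three-letter sense codon (character, e.g. `"GGG"`).
#' @param position Codon position, 1, 2 or 3.
#' @return Integer degeneracy class: 0, 2 or 4.
#' @export
codon_site_degeneracy <- function(codon, position) {
  code <- genetic_code()
  codon <- toupper(codon)
  aa <- code[codon]
  if (is.na(aa)) stop("invalid codon: ", codon, call. = FALSE)
  if (aa == "*") stop("stop codon has no degeneracy class: ", codon,
                      call. = FALSE)
  stopifnot(position %in% 1:3)
  nt <- strsplit(codon, "")[[1]]
  syn <- 0L
  for (b in setdiff(NUCS, nt[position])) {
    alt <- nt; alt[position] <- b
    aa2 <- code[paste(alt, collapse = "")]
    if (!is.na(aa2) && aa2 != "*" && aa2 == aa) syn <- syn + 1L
  }
  if (syn == 3L) 4L else if (syn >= 1L) 2L else 0L
}

# degeneracy classes for all 3 positions of every sense codon, precomputed
degeneracy_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      code <- genetic_code()
      sense <- names(code)[code != "*"]
      m <- matrix(NA_integer_, length(sense), 3,
                  dimnames = list(sense, NULL))
      for (cd in sense) for (p in 1:3)
        m[cd, p] <- codon_site_degeneracy(cd, p)
      tab <<- m
    }
    tab
  }
})

split_codons <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  if (n %% 3 != 0)
    stop("frame error: sequence length not divisible by 3", call. = FALSE)
  substring(s, seq(1, n, 3), seq(3, n, 3))
}

translate_cds <- function(s) {
  as.character(Biostrings::translate(Biostrings::DNAString(toupper(s)),
                                     if.fuzzy.codon = "X"))
}

#' Thread unaligned coding sequences onto a protein alignment
#'
#' Expands each amino-acid column of a protein multiple alignment to the
#' corresponding codon of the (unaligned) coding sequence; protein gaps become
#' `---`. Terminal stop codons on the coding sequences are trimmed. Every
#' coding sequence must translate exactly to its ungapped protein row.
#'
#' @param protein_aln Named character vector of aligned protein sequences
#'   (gap `-`), or a path to a FASTA file.
#' @param cds Named character vector of unaligned coding sequences, or a path
#'   to a FASTA file. Names must match `protein_aln`.
#' @param drop_bad Drop (with a warning) sequences with internal stops or
#'   length mismatches instead of erroring.
#' @return Named character vector of aligned codon sequences (class
#'   `codon_alignment`), rows of equal length divisible by 3.
#' @export
thread_codon_alignment <- function(protein_aln, cds, drop_bad = FALSE) {
  if (is.character(protein_aln) && length(protein_aln) == 1 &&
      file.exists(protein_aln)) protein_aln <- read_fasta(protein_aln)
  if (is.character(cds) && length(cds) == 1 && file.exists(cds))
    cds <- read_fasta(cds)
  ids <- names(protein_aln)
  if (is.null(ids) || !all(ids %in% names(cds)))
    stop("every protein row needs a matching coding sequence", call. = FALSE)
  out <- character(0)
  for (id in ids) {
    prot <- toupper(protein_aln[[id]])
    seq <- toupper(cds[[id]])
    ungapped <- gsub("-", "", prot)
    bad <- NULL
    aa_full <- ""
    if (nchar(seq) %% 3 == 0 && nchar(seq) >= 3) {
      aa_full <- translate_cds(seq)
      if (substring(aa_full, nchar(aa_full)) == "*") {  # trim terminal stop
        seq <- substring(seq, 1, nchar(seq) - 3)
        aa_full <- substring(aa_full, 1, nchar(aa_full) - 1)
      }
    }
    if (nchar(seq) %% 3 != 0 || nchar(seq) < 3)
      bad <- paste0("frame error for '", id, "'")
    else if (nchar(aa_full) != nchar(ungapped))
      bad <- paste0("length mismatch for '", id, "'")
    else if (grepl("\\*", aa_full))
      bad <- paste0("internal stop codon in '", id, "'")
    else if (aa_full != ungapped) {
      pos <- which(strsplit(aa_full, "")[[1]] != strsplit(ungapped, "")[[1]])[1]
      bad <- paste0("translation mismatch for '", id, "' at protein position ",
                    pos)
    }
    if (!is.null(bad)) {
      if (drop_bad) { warning(bad, "; sequence omitted", call. = FALSE); next }
      stop(bad, call. = FALSE)
    }
    codons <- split_codons(seq)
    cols <- strsplit(prot, "")[[1]]
    row <- character(length(cols))
    j <- 0L
    for (k in seq_along(cols)) {
      if (cols[k] == "-") row[k] <- "---"
      else { j <- j + 1L; row[k] <- codons[j] }
    }
    out[id] <- paste(row, collapse = "")
  }
  if (!length(out))
    stop("no sequences survived threading", call. = FALSE)
  structure(out, class = "codon_alignment")
}

#' Read / write FASTA as named character vectors
#'
#' Thin wrappers around Biostrings' FASTA reader for plain sequence vectors.
#'
#' @param path File path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  invisible(path)
}
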