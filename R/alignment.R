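## Alignments are stored as a character matrix (rows = sequences, columns =
## sites) over the alphabet {A,C,G,T,-,N}, with unique row names. This keeps
## column resampling (bootstrap), pairwise comparisons and haplotype collapse
## cheap and transparent at the sizes single-locus delimitation works with.

ALN_ALPHABET <- c("A", "C", "G", "T", "-", "N")

#' Construct an alignment object
#'
#' An `alignment` is a character matrix of aligned nucleotides (rows =
#' sequences, columns = sites) restricted to the alphabet `A C G T - N`.
#' IUPAC ambiguity codes other than `N` are degraded to `N` with a warning;
#' lower case is folded to upper case.
#'
#' @param seqs Character vector of equal-length sequence strings.
#' @param labels Character vector of unique, non-empty labels (defaults to
#'   `names(seqs)`).
#' @return An object of class `alignment`: a character matrix with attributes.
#' @examples
#' aln <- alignment(c(a = "ACGT", b = "ACGA"))
#' aln_length(aln)
#' @export
alignment <- function(seqs, labels = names(seqs)) {
  if (length(seqs) == 0L) stop("alignment must contain at least one sequence")
  if (is.null(labels)) stop("sequence labels are required")
  labels <- as.character(labels)
  if (anyNA(labels) || any(!nzchar(labels))) stop("labels must be non-empty")
  if (anyDuplicated(labels)) {
    stop("duplicate labels: ", paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  seqs <- toupper(as.character(seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- labels[lens != lens[1L]][1L]
    stop("unequal sequence lengths: record '", bad, "' has ", nchar(seqs[labels == bad]),
         " sites, expected ", lens[1L])
  }
  if (lens[1L] < 1L) stop("alignment length must be >= 1")
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE,
                dimnames = list(labels, NULL))
  bad <- !(mat %in% ALN_ALPHABET)
  if (any(bad)) {
    warning(sum(bad), " ambiguous/non-standard base(s) replaced by N")
    mat[bad] <- "N"
  }
  structure(mat, class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("alignment: ", nrow(x), " sequences, ", ncol(x), " sites\n", sep = "")
  show <- utils::head(rownames(x), 6L)
  for (lab in show) {
    s <- paste(x[lab, seq_len(min(50L, ncol(x)))], collapse = "")
    cat(sprintf("  %-20s %s%s\n", lab, s, if (ncol(x) > 50L) "..." else ""))
  }
  if (nrow(x) > 6L) cat("  ... and ", nrow(x) - 6L, " more\n", sep = "")
  invisible(x)
}

#' Number of sites in an alignment
#' @param aln An `alignment`.
#' @return Integer number of columns.
#' @export
aln_length <- function(aln) ncol(aln)

#' Sequence labels of an alignment
#' @param aln An `alignment`.
#' @return Character vector of labels in order.
#' @export
aln_labels <- function(aln) rownames(aln)

#' Subset an alignment by label
#' @param aln An `alignment`.
#' @param labels Labels to keep, in the given order.
#' @return An `alignment` with the selected records.
#' @export
aln_subset <- function(aln, labels) {
  missing <- setdiff(labels, rownames(aln))
  if (length(missing)) stop("labels not in alignment: ", paste(missing, collapse = ", "))
  structure(aln[labels, , drop = FALSE], class = "alignment")
}

aln_strings <- function(aln) {
  stats::setNames(apply(unclass(aln), 1L, paste, collapse = ""), rownames(aln))
}

#' Read a FASTA alignment
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped lines) into an
#' [alignment()]. All records must have the same length; labels (the full
#' header line after `>`) must be unique.
#'
#' @param path Path to a FASTA file.
#' @return An `alignment`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  hdr <- startsWith(lines, ">")
  if (!hdr[1L]) stop("not FASTA: first non-blank line must start with '>'")
  idx <- cumsum(hdr)
  labels <- trimws(sub("^>", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, character(1L), collapse = "")
  if (length(seqs) != length(labels)) stop("FASTA record without sequence lines")
  seqs <- gsub("[[:space:]]", "", seqs)
  alignment(seqs, labels)
}

#' Write a FASTA alignment
#'
#' Sequences are written unwrapped, one line per record. Round-trips through
#' [read_fasta()] exactly.
#'
#' @param aln An `alignment`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "alignment"))
  seqs <- aln_strings(aln)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", names(seqs), "\n", seqs), con, sep = "\n")
  invisible(path)
}

#' Collapse identical sequences to unique haplotypes
#'
#' Returns the alignment pruned to one representative per distinct sequence
#' string (the first occurrence wins) together with the map from every
#' original label to its representative. This is the "pruned" data set used
#' to stabilise GMYC fits when duplicate haplotypes are present.
#'
#' @param aln An `alignment`.
#' @return A list with elements `alignment` (pruned) and `map` (a data frame
#'   with columns `label` and `representative`).
#' @export
collapse_haplotypes <- function(aln) {
  seqs <- aln_strings(aln)
  rep_idx <- match(seqs, seqs)            # first occurrence of each string
  map <- data.frame(label = names(seqs),
                    representative = names(seqs)[rep_idx],
                    stringsAsFactors = FALSE)
  keep <- !duplicated(seqs)
  list(alignment = structure(unclass(aln)[keep, , drop = FALSE], class = "alignment"),
       map = map)
}

#' Write a haplotype map as TSV
#' @param map Data frame from [collapse_haplotypes()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_haplotype_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
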