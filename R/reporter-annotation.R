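#' Reporter annotation: a pre-mRNA region plus its exon/intron layout
#'
#' Bundles the sense-strand sequence of the screened pre-mRNA region with an
#' ordered feature table (label, start, end in 0-based half-open coordinates).
#' Features must tile the sequence without gaps or overlaps. The canonical
#' layout for a cassette-exon reporter uses labels `exon6`, `intron6`,
#' `exon7`, `intron7`, `exon8`; free-form labels are allowed, but the
#' splice-site-relative guide naming (`A`/`E`/`D`) needs the canonical trio
#' `intron6`/`exon7`/`intron7`.
#'
#' @param sequence Single nucleotide string (alphabet A/C/G/T/N).
#' @param features Data frame with columns `label`, `start`, `end`
#'   (0-based half-open, within `[0, nchar(sequence)]`).
#' @return An object of class `reporter_annotation`: a list with elements
#'   `sequence` (string) and `features` (tibble).
#' @export
reporter_annotation <- function(sequence, features) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (stringr::str_detect(sequence, "[^ACGTN]")) {
    stop("sequence contains characters outside A/C/G/T/N", call. = FALSE)
  }
  features <- tibble::as_tibble(features)
  stopifnot(all(c("label", "start", "end") %in% names(features)))
  features <- dplyr::arrange(features, .data$start)
  len <- nchar(sequence)
  if (nrow(features) > 0) {
    if (any(features$start < 0) || any(features$end > len) ||
        any(features$end <= features$start)) {
      stop("feature boundaries must satisfy 0 <= start < end <= length(sequence)",
           call. = FALSE)
    }
    gaps <- c(features$start[1] != 0,
              utils::head(features$end, -1) != features$start[-1],
              features$end[nrow(features)] != len)
    if (any(gaps)) {
      stop("features must tile the sequence without gaps or overlaps",
           call. = FALSE)
    }
  }
  structure(list(sequence = sequence, features = features),
            class = "reporter_annotation")
}

#' @export
print.reporter_annotation <- function(x, ...) {
  cat("<reporter_annotation> ", nchar(x$sequence), " nt, ",
      nrow(x$features), " features\n", sep = "")
  print(x$features, ...)
  invisible(x)
}

#' Look up one feature interval by label
#'
#' @param annotation A [reporter_annotation()].
#' @param label Feature label to retrieve.
#' @return Named list with `start` and `end` (0-based half-open), or `NULL`
#'   when the label is absent.
#' @export
feature_interval <- function(annotation, label) {
  stopifnot(inherits(annotation, "reporter_annotation"))
  hit <- dplyr::filter(annotation$features, .data$label == !!label)
  if (nrow(hit) == 0) return(NULL)
  list(start = hit$start[1], end = hit$end[1])
}

#' Read a reporter annotation from FASTA + feature table
#'
#' The feature table is BED-like: tab-separated, no header required when the
#' file has exactly three columns (`label`, `start`, `end`), 0-based
#' half-open.
#'
#' @param fasta Path to a single-record FASTA file.
#' @param features_tsv Path to the feature table.
#' @return A [reporter_annotation()].
#' @export
read_reporter_annotation <- function(fasta, features_tsv) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L) {
    stop("expected exactly one FASTA record, got ", length(seqs), call. = FALSE)
  }
  feats <- utils::read.table(features_tsv, sep = "\t", header = FALSE,
                             col.names = c("label", "start", "end"),
                             stringsAsFactors = FALSE)
  reporter_annotation(as.character(seqs[[1]]), feats)
}

#' Write a reporter annotation to FASTA + feature table
#'
#' @param annotation A [reporter_annotation()].
#' @param fasta,features_tsv Output paths.
#' @return Invisibly, the annotation.
#' @export
write_reporter_annotation <- function(annotation, fasta, features_tsv) {
  stopifnot(inherits(annotation, "reporter_annotation"))
  seq <- Biostrings::DNAStringSet(annotation$sequence)
  names(seq) <- "reporter"
  Biostrings::writeXStringSet(seq, fasta)
  utils::write.table(annotation$features[, c("label", "start", "end")],
                     features_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(annotation)
}

#' Demo cassette-exon reporter annotation
#'
#' A synthetic 835-nt reporter region laid out as exon6 (81 nt), intron6
#' (200 nt), exon7 (54 nt), intron7 (444 nt), exon8 (56 nt), with a random
#' sequence drawn under the given seed. The layout mimics a truncated SMN2
#' minigene spanning exon 6 to exon 8; the sequence itself is synthetic.
#'
#' @param seed Integer seed for the random sequence.
#' @return A [reporter_annotation()].
#' @export
demo_annotation <- function(seed = 1L) {
  seq <- random_dna(835L, seed = seed)
  feats <- tibble::tibble(
    label = c("exon6", "intron6", "exon7", "intron7", "exon8"),
    start = c(0L, 81L, 281L, 335L, 779L),
    end   = c(81L, 281L, 335L, 779L, 835L)
  )
  reporter_annotation(seq, feats)
}

#' Random DNA string
#'
#' @param n Length in nucleotides.
#' @param seed Optional integer seed (uses the current RNG state when `NULL`).
#' @return A single string over A/C/G/T.
#' @export
random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse complement of nucleotide strings
#'
#' Thin vectorized wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
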