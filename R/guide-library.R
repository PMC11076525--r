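#' Tile guide RNAs across a reporter region
#'
#' Enumerates every window of each requested spacer length at the given step
#' and emits one guide per window. The spacer is the reverse complement of
#' the target window (the guide is antisense to the pre-mRNA), so for a
#' window `[start, end)` of length L, `spacer == reverse_complement(sequence[start:end])`.
#' Windows containing `N` are emitted but flagged (`flagged_n`).
#'
#' @param annotation A [reporter_annotation()].
#' @param lengths Integer vector of spacer lengths (typically `c(22, 25)`).
#' @param step Tiling step in nt (>= 1); 1 gives full single-nucleotide tiling.
#' @return Tibble with columns `length`, `target_start`, `target_end`
#'   (0-based half-open on the reporter), `spacer`, `flagged_n`, ordered by
#'   `(length, target_start)`. A length longer than the region contributes no
#'   rows (with a warning).
#' @export
tile_guides <- function(annotation, lengths = c(22L, 25L), step = 1L) {
  stopifnot(inherits(annotation, "reporter_annotation"), step >= 1)
  len <- nchar(annotation$sequence)
  purrr::map_dfr(sort(unique(as.integer(lengths))), function(L) {
    if (L > len) {
      warning("spacer length ", L, " exceeds region length ", len,
              "; no guides emitted for this length", call. = FALSE)
      return(tibble::tibble(length = integer(), target_start = integer(),
                            target_end = integer(), spacer = character(),
                            flagged_n = logical()))
    }
    starts <- seq.int(0L, len - L, by = step)
    windows <- stringr::str_sub(annotation$sequence, starts + 1L, starts + L)
    tibble::tibble(
      length = L,
      target_start = starts,
      target_end = starts + L,
      spacer = reverse_complement(windows),
      flagged_n = stringr::str_detect(windows, "N")
    )
  })
}

# Position of a target base relative to a junction feature, using the
# no-zero convention: first base of `feature` is +1, the base immediately
# 5' of it is -1.
.junction_pos <- function(i, boundary) {
  ifelse(i >= boundary, i - boundary + 1L, i - boundary)
}

#' Name guides by the splice-site-relative convention
#'
#' On-target guides are named relative to the monitored cassette exon:
#' `E[a,b]` for guides fully inside the exon (1-based from the exon start),
#' `D[a,b]` for guides inside the downstream intron or spanning the 5'
#' splice site (intron position 1 is the first intronic base; exonic
#' positions are negative, counted back from the exon's last base; there is
#' no position 0), and `A[a,b]` for guides inside the upstream intron or
#' spanning the 3' splice site (exon position 1 is the first exonic base;
#' intronic positions are negative, counted back from the intron's last
#' base). Guides outside the `intron6`/`exon7`/`intron7` window, or guides
#' on an annotation lacking those labels, get absolute 1-based inclusive
#' names `abs[start,end]`.
#'
#' @param guides Tibble with `target_start`, `target_end` columns (as from
#'   [tile_guides()]).
#' @param annotation The [reporter_annotation()] used for tiling.
#' @return The input tibble with a `name` column added.
#' @export
name_guides <- function(guides, annotation) {
  stopifnot(inherits(annotation, "reporter_annotation"))
  i6 <- feature_interval(annotation, "intron6")
  e7 <- feature_interval(annotation, "exon7")
  i7 <- feature_interval(annotation, "intron7")
  s <- guides$target_start
  e <- guides$target_end
  name <- sprintf("abs[%d,%d]", s + 1L, e)
  if (!is.null(i6) && !is.null(e7) && !is.null(i7)) {
    in_e7 <- s >= e7$start & e <= e7$end
    # D window: inside intron7 or spanning the exon7/intron7 junction
    d <- !in_e7 & s >= e7$start & e <= i7$end & e > i7$start
    # A window: inside intron6 or spanning the intron6/exon7 junction
    a <- !in_e7 & !d & s >= i6$start & e <= e7$end
    name[in_e7] <- sprintf("E[%d,%d]",
                           s[in_e7] - e7$start + 1L, e[in_e7] - e7$start)
    name[d] <- sprintf("D[%d,%d]",
                       .junction_pos(s[d], i7$start),
                       .junction_pos(e[d] - 1L, i7$start))
    name[a] <- sprintf("A[%d,%d]",
                       .junction_pos(s[a], e7$start),
                       .junction_pos(e[a] - 1L, e7$start))
  }
  dplyr::mutate(guides, name = name)
}

#' Name a single on-target guide
#'
#' @param target_start,target_end 0-based half-open target interval.
#' @param annotation The [reporter_annotation()].
#' @return The name string (see [name_guides()]).
#' @export
name_guide <- function(target_start, target_end, annotation) {
  if (is.na(target_start) || is.na(target_end)) {
    stop("control guides have no target interval and cannot be named by position",
         call. = FALSE)
  }
  name_guides(tibble::tibble(target_start = target_start,
                             target_end = target_end), annotation)$name
}

#' Parse a splice-site-relative guide name back to its target interval
#'
#' Inverse of [name_guides()] for guides within the named window.
#'
#' @param name Guide name such as `"D[9,30]"` or `"abs[100,124]"`.
#' @param annotation The [reporter_annotation()].
#' @return Named list with 0-based half-open `target_start`, `target_end`.
#' @export
parse_guide_name <- function(name, annotation) {
  m <- stringr::str_match(name, "^(E|A|D|abs)\\[(-?\\d+),(-?\\d+)\\]$")
  if (any(is.na(m[, 1]))) stop("unparseable guide name: ", name, call. = FALSE)
  kind <- m[, 2]
  a <- as.integer(m[, 3])
  b <- as.integer(m[, 4])
  e7 <- feature_interval(annotation, "exon7")
  i7 <- feature_interval(annotation, "intron7")
  from_junction <- function(p, boundary) {
    ifelse(p > 0, boundary + p - 1L, boundary + p)
  }
  start <- switch(kind,
    abs = a - 1L,
    E = e7$start + a - 1L,
    D = from_junction(a, i7$start),
    A = from_junction(a, e7$start)
  )
  end <- switch(kind,
    abs = b,
    E = e7$start + b,
    D = from_junction(b, i7$start) + 1L,
    A = from_junction(b, e7$start) + 1L
  )
  list(target_start = start, target_end = end)
}

#' Generate control guide spacers
#'
#' Non-targeting controls are uniform random ACGT strings, rejection-sampled
#' so that neither the spacer nor its reverse complement occurs as an exact
#' substring of any forbidden sequence (typically the reporter; a genome-
#' scale exclusion list can be supplied by the caller). Sense controls copy
#' a target window on the sense strand (same sequence as the pre-mRNA, so
#' they cannot base-pair with it).
#'
#' @param n Number of controls.
#' @param length Spacer length.
#' @param forbidden Character vector of sequences controls must not match
#'   (required for non-targeting controls when `n > 0`).
#' @param seed Integer seed (sampling is reproducible).
#' @param kind `"non_targeting"` or `"sense"`.
#' @param annotation Required for `kind = "sense"`: windows are drawn from it.
#' @param max_retries Rejection-sampling cap per control.
#' @return Tibble with columns `spacer`, `control_kind`.
#' @export
generate_controls <- function(n, length = 25L, forbidden = character(),
                              seed = 1L, kind = c("non_targeting", "sense"),
                              annotation = NULL, max_retries = 10000L) {
  kind <- match.arg(kind)
  if (n == 0) {
    return(tibble::tibble(spacer = character(), control_kind = character()))
  }
  set.seed(seed)
  if (kind == "sense") {
    stopifnot(inherits(annotation, "reporter_annotation"))
    len <- nchar(annotation$sequence)
    starts <- sample.int(len - length + 1L, n, replace = TRUE) - 1L
    return(tibble::tibble(
      spacer = stringr::str_sub(annotation$sequence, starts + 1L, starts + length),
      control_kind = "sense"
    ))
  }
  if (length(forbidden) == 0) {
    stop("non-targeting controls require a non-empty forbidden sequence list",
         call. = FALSE)
  }
  spacers <- character(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      cand <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                    collapse = "")
      hits <- vapply(forbidden, function(f) {
        stringr::str_detect(f, stringr::fixed(cand)) ||
          stringr::str_detect(f, stringr::fixed(reverse_complement(cand)))
      }, logical(1))
      if (!any(hits) && !cand %in% spacers[seq_len(i - 1L)]) {
        spacers[i] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("control generation exceeded the retry cap (", max_retries,
           " attempts); relax the forbidden list or shorten it", call. = FALSE)
    }
  }
  tibble::tibble(spacer = spacers, control_kind = "non_targeting")
}

# Default RfxCas13d direct repeat and cloning adapters; overridable in
# design_guide_library().
default_dr_seq <- function() "AACCCCTACCAACTGGTCGGGGTTTGAAAC"
default_adapters <- function() {
  list(five_prime = "ATCTTGTGGAAAGGACGAAACACC",
       three_prime = "GTTTTAGAGCTAAGCTGGAAACAGCA")
}

#' Design a full tiling guide library
#'
#' Tiles the reporter at every requested length, names guides by the
#' splice-site-relative convention, appends non-targeting controls, and
#' attaches the direct-repeat and adapter sequences used for oligo assembly
#' and spacer counting. Guide ids are `{name}_{length}` for on-target guides
#' and `NT{i}_{length}` for controls, with a numeric suffix on collision.
#'
#' @param annotation A [reporter_annotation()].
#' @param lengths Spacer lengths to tile.
#' @param step Tiling step (nt).
#' @param n_controls Number of non-targeting controls.
#' @param control_length Spacer length for controls.
#' @param seed Seed for control generation.
#' @param dr_seq Direct-repeat sequence placed 5' of the spacer in the oligo.
#' @param adapters List with `five_prime` and `three_prime` adapter strings.
#' @return A `guide_library`: a tibble with columns `id`, `name`, `length`,
#'   `target_start`, `target_end`, `spacer`, `is_control`, `control_kind`,
#'   `flagged_n`, carrying the annotation, DR and adapters as attributes.
#' @export
design_guide_library <- function(annotation, lengths = c(22L, 25L), step = 1L,
                                 n_controls = 312L, control_length = 25L,
                                 seed = 1L, dr_seq = default_dr_seq(),
                                 adapters = default_adapters()) {
  on_target <- tile_guides(annotation, lengths, step)
  on_target <- name_guides(on_target, annotation)
  on_target <- dplyr::mutate(on_target, is_control = FALSE,
                             control_kind = "none")
  forbidden <- annotation$sequence
  # windows containing N are excluded from the control-forbidden check by
  # construction: controls are pure ACGT so cannot match an N position anyway
  ctrl <- generate_controls(n_controls, control_length, forbidden, seed = seed)
  if (nrow(ctrl) > 0) {
    ctrl <- dplyr::mutate(ctrl,
      name = sprintf("NT%03d", dplyr::row_number()),
      length = as.integer(control_length),
      target_start = NA_integer_, target_end = NA_integer_,
      is_control = TRUE, flagged_n = FALSE)
  }
  lib <- dplyr::bind_rows(on_target, ctrl)
  ids <- paste0(lib$name, "_", lib$length)
  dup <- ids %in% ids[duplicated(ids)]
  if (any(dup)) {
    ids[dup] <- paste0(ids[dup], "_", stats::ave(seq_along(ids)[dup],
                                                 ids[dup], FUN = seq_along))
  }
  lib <- dplyr::mutate(lib, id = ids, .before = 1)
  lib <- dplyr::select(lib, "id", "name", "length", "target_start",
                       "target_end", "spacer", "is_control", "control_kind",
                       "flagged_n")
  structure(lib, class = c("guide_library", class(lib)),
            annotation = annotation, dr_seq = dr_seq, adapters = adapters)
}

#' @export
print.guide_library <- function(x, ...) {
  cat("<guide_library> ", nrow(x), " guides (",
      sum(!x$is_control), " on-target, ", sum(x$is_control), " controls)\n",
      sep = "")
  NextMethod()
}

#' Assemble synthesis oligos for a guide library
#'
#' Each oligo is `five_prime + DR + spacer + three_prime`; [extract_spacers()]
#' inverts the assembly.
#'
#' @param library A [design_guide_library()] result (or any tibble with `id`
#'   and `spacer` plus `dr_seq`/`adapters` attributes or explicit arguments).
#' @param dr_seq,adapters Override the library's attached DR/adapters.
#' @return Tibble with columns `id`, `oligo`.
#' @export
assemble_oligos <- function(library, dr_seq = attr(library, "dr_seq"),
                            adapters = attr(library, "adapters")) {
  if (is.null(dr_seq) || !nzchar(dr_seq)) {
    stop("direct-repeat sequence must be non-empty", call. = FALSE)
  }
  stopifnot(!is.null(adapters$five_prime), !is.null(adapters$three_prime))
  tibble::tibble(
    id = library$id,
    oligo = paste0(adapters$five_prime, dr_seq, library$spacer,
                   adapters$three_prime)
  )
}

#' Extract spacers back out of assembled oligos
#'
#' @param oligos Tibble from [assemble_oligos()].
#' @param dr_seq,adapters The DR/adapter sequences used for assembly.
#' @return Tibble with columns `id`, `spacer`.
#' @export
extract_spacers <- function(oligos, dr_seq, adapters) {
  prefix <- paste0(adapters$five_prime, dr_seq)
  spacer <- stringr::str_sub(oligos$oligo, nchar(prefix) + 1L,
                             nchar(oligos$oligo) - nchar(adapters$three_prime))
  tibble::tibble(id = oligos$id, spacer = spacer)
}

#' Write / read a guide library as TSV
#'
#' The TSV holds the guide table; the annotation, DR and adapters travel in
#' a JSON sidecar (`<path>.json`) so the library round-trips.
#'
#' @param library A guide library tibble.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_guide_library <- function(library, path) {
  readr::write_tsv(tibble::as_tibble(library), path, na = ".")
  ann <- attr(library, "annotation")
  meta <- list(dr_seq = attr(library, "dr_seq"),
               adapters = attr(library, "adapters"))
  if (!is.null(ann)) {
    meta$sequence <- ann$sequence
    meta$features <- as.data.frame(ann$features)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_guide_library
#' @export
read_guide_library <- function(path) {
  lib <- readr::read_tsv(path, na = ".", show_col_types = FALSE,
                         progress = FALSE)
  sidecar <- paste0(path, ".json")
  ann <- NULL
  dr <- default_dr_seq()
  adapters <- default_adapters()
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$sequence)) {
      ann <- reporter_annotation(meta$sequence, meta$features)
    }
    if (!is.null(meta$dr_seq)) dr <- meta$dr_seq
    if (!is.null(meta$adapters)) adapters <- as.list(meta$adapters)
  }
  structure(lib, class = c("guide_library", class(lib)),
            annotation = ann, dr_seq = dr, adapters = adapters)
}

#' Write assembled oligos as FASTA
#'
#' @param oligos Tibble from [assemble_oligos()].
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_oligos_fasta <- function(oligos, path) {
  seqs <- Biostrings::DNAStringSet(oligos$oligo)
  names(seqs) <- oligos$id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Plot anchor position of each guide
#'
#' The reporting anchor of a guide is its 5'-most target coordinate (the
#' base paired by the 3' end of the spacer), 1-based.
#'
#' @param library A guide library tibble.
#' @return Integer vector of anchor positions (NA for controls).
#' @export
guide_anchor <- function(library) {
  library$target_start + 1L
}
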