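#' Read a gene/operon annotation
#'
#' Accepts GFF3 (via \pkg{rtracklayer}) or TSV.  TSV files need columns
#' `gene`, `start`, `end`, `strand` and optionally `operon`,
#' `operon_pos`; GFF3 records carry the same information in the `ID`,
#' `operon` and `operon_pos` attributes.  Coordinates are 1-based
#' inclusive; strand must be `+` or `-`.
#'
#' @param path annotation file path (`.gff`/`.gff3` or TSV).
#' @return Annotation tibble as produced by [generate_genome()].
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("reading GFF3 requires the rtracklayer package.")
    }
    gr <- rtracklayer::import(path)
    tb <- tibble::tibble(
      gene = as.character(gr$ID),
      start = BiocGenerics::start(gr),
      end = BiocGenerics::end(gr),
      strand = as.character(BiocGenerics::strand(gr)),
      operon = as.character(gr$operon %||% NA_character_),
      operon_pos = as.integer(gr$operon_pos %||% NA_integer_)
    )
    tb$length <- tb$end - tb$start + 1
  } else {
    tb <- readr::read_tsv(path, show_col_types = FALSE)
    req <- c("gene", "start", "end", "strand")
    miss <- setdiff(req, names(tb))
    if (length(miss) > 0) {
      abort(paste0("annotation is missing column(s): ",
                   paste(miss, collapse = ", ")))
    }
    tb$length <- tb$end - tb$start + 1
  }
  check_rows(tb$strand %in% c("+", "-"), "invalid strand (want + or -)")
  check_rows(tb$start >= 1, "start coordinate below 1 (coordinates are 1-based)")
  check_rows(tb$end >= tb$start, "end before start")
  tibble::as_tibble(tb)
}

#' Write a synthetic genome as GFF3
#'
#' @param genome annotation tibble from [generate_genome()].
#' @param path output path.
#' @param seqname sequence name for the single synthetic replicon.
#' @return `path`, invisibly.
#' @export
write_genome_gff3 <- function(genome, path, seqname = "synthetic") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("writing GFF3 requires the rtracklayer package.")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(genome$start, genome$end),
    strand = genome$strand,
    type = "gene", ID = genome$gene,
    operon = genome$operon, operon_pos = genome$operon_pos
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a per-gene mRNA half-life table
#'
#' The TSV must carry columns `gene`, `half_life` and `unit`
#' (`s`/`seconds` or `min`/`minutes`); a missing unit column is a hard
#' error — seconds vs. minutes is never guessed.  Minutes are converted
#' to seconds.
#'
#' @param path TSV path.
#' @return Tibble `gene`, `half_life` (seconds).
#' @export
read_half_lives <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  miss <- setdiff(c("gene", "half_life", "unit"), names(tb))
  if (length(miss) > 0) {
    abort(paste0("half-life table is missing column(s): ",
                 paste(miss, collapse = ", "),
                 if ("unit" %in% miss) " (the unit is never guessed)" else ""))
  }
  check_rows(tb$unit %in% c("s", "seconds", "min", "minutes"),
             "unknown half-life unit (want s/seconds or min/minutes)")
  check_rows(is.finite(tb$half_life) & tb$half_life > 0,
             "non-positive half-life")
  tibble::tibble(
    gene = tb$gene,
    half_life = tb$half_life * ifelse(tb$unit %in% c("min", "minutes"), 60, 1)
  )
}

#' Read / write probe-level track TSVs
#'
#' Columns `coordinate` (1-based nt), `strand` (`+`, `-` or `both`),
#' `replicate`, `intensity`.
#'
#' @param path TSV path.
#' @return [read_probe_track()]: the validated probe tibble.
#' @export
read_probe_track <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  miss <- setdiff(c("coordinate", "strand", "replicate", "intensity"),
                  names(tb))
  if (length(miss) > 0) {
    abort(paste0("probe track is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  check_rows(tb$strand %in% c("+", "-", "both"),
             "invalid strand (want +, - or both)")
  check_rows(tb$coordinate >= 1, "coordinate below 1 (coordinates are 1-based)")
  tibble::as_tibble(tb)
}

#' @rdname read_probe_track
#' @param track probe tibble.
#' @export
write_probe_track <- function(track, path) {
  readr::write_tsv(track, path)
  invisible(path)
}

#' Read / write a speed table TSV
#'
#' @param path TSV path.
#' @export
read_speed_table <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"gene" %in% names(tb)) abort("speed table needs a `gene` column.")
  tibble::as_tibble(tb)
}

#' @rdname read_speed_table
#' @param speed_table speed-table tibble.
#' @export
write_speed_table <- function(speed_table, path) {
  readr::write_tsv(speed_table, path)
  invisible(path)
}

# Abort naming the first offending row.
check_rows <- function(ok, what) {
  if (any(!ok)) {
    abort(paste0(what, " at row ", which(!ok)[1], " (", sum(!ok),
                 " row(s) affected)."))
  }
  invisible(TRUE)
}
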