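STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "GTG", "TTG")

# The 61 sense codons in a fixed lexicographic order.
sense_codons <- function() {
  all <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                               paste0), c("A", "C", "G", "T"), paste0))
  sort(setdiff(all, STOP_CODONS))
}

#' Per-gene codon-usage features
#'
#' Computes, for each coding sequence, the relative frequency of each of
#' the 61 sense codons (stop codons excluded from numerator and
#' denominator), GC content at the three codon positions, and — when a
#' tRNA anticodon inventory is supplied — the frequency of codons read
#' exclusively through wobble pairing at the third position (`strict`)
#' and of codons read by both wobble- and Watson-Crick-pairing anticodons
#' (`mixed`).
#'
#' @param cds named character vector of DNA coding sequences, or a
#'   `Biostrings::DNAStringSet` (e.g. from
#'   `Biostrings::readDNAStringSet()`).  Sequences whose length is not a
#'   multiple of 3 are skipped with a warning; a missing start codon only
#'   warns.
#' @param anticodons optional tibble with column `anticodon` (DNA
#'   alphabet, 5'->3') listing the tRNA anticodons present; see
#'   [wobble_codon_classes()].
#' @return Tibble with one row per gene: `gene`, `length` (nt),
#'   `n_codons` (sense codons), `gc1`, `gc2`, `gc3`, one `freq_<codon>`
#'   column per sense codon, and (with `anticodons`)
#'   `wobble_strict_freq`, `wobble_mixed_freq`.
#' @examples
#' codon_features(c(g1 = "ATGGCG"))
#' @export
codon_features <- function(cds, anticodons = NULL) {
  if (inherits(cds, "DNAStringSet")) {
    cds <- setNames(as.character(cds), names(cds))
  }
  if (is.null(names(cds)) || any(names(cds) == "")) {
    abort("`cds` sequences must be named by gene id.")
  }
  cds <- toupper(gsub("U", "T", cds))
  bad <- names(cds)[nchar(cds) %% 3 != 0]
  if (length(bad) > 0) {
    warn(paste0("skipping gene(s) whose CDS length is not a multiple of 3: ",
                paste(head(bad, 5), collapse = ", ")))
    cds <- cds[!names(cds) %in% bad]
  }
  if (length(cds) == 0) abort("no valid coding sequences left.")
  no_start <- names(cds)[!substr(cds, 1, 3) %in% START_CODONS]
  if (length(no_start) > 0) {
    warn(paste0(length(no_start), " CDS without a bacterial start codon: ",
                paste(head(no_start, 5), collapse = ", ")))
  }
  sense <- sense_codons()
  classes <- if (!is.null(anticodons)) wobble_codon_classes(anticodons)
  purrr::imap_dfr(cds, function(seq, gene) {
    cods <- substring(seq, seq(1, nchar(seq) - 2, 3), seq(3, nchar(seq), 3))
    cods <- cods[!cods %in% STOP_CODONS]
    counts <- table(factor(cods, levels = sense))
    freq <- as.numeric(counts) / length(cods)
    bases <- matrix(unlist(strsplit(cods, "")), nrow = 3)
    out <- tibble::tibble(
      gene = gene, length = nchar(seq), n_codons = length(cods),
      gc1 = mean(bases[1, ] %in% c("G", "C")),
      gc2 = mean(bases[2, ] %in% c("G", "C")),
      gc3 = mean(bases[3, ] %in% c("G", "C"))
    )
    out[paste0("freq_", sense)] <- as.list(freq)
    if (!is.null(classes)) {
      out$wobble_strict_freq <- mean(cods %in% classes$strict)
      out$wobble_mixed_freq <- mean(cods %in% classes$mixed)
    }
    out
  })
}

#' Classify sense codons by third-position pairing mode
#'
#' Given the tRNA anticodon inventory, each anticodon reads its exact
#' reverse-complement codon by Watson-Crick pairing and, depending on its
#' 5' (position 34) base, additional codons by wobble pairing: G34 also
#' reads third-position U; U34 also reads third-position G; A34 is taken
#' as inosine (its near-universal modification) and additionally reads
#' third-position C and A; C34 pairs strictly.  A codon read only through
#' wobble interactions is `strict`; one with both wobble and Watson-Crick
#' readers is `mixed`.
#'
#' @param anticodons tibble (or data frame) with column `anticodon`,
#'   DNA alphabet, written 5'->3'.
#' @return List with character vectors `strict`, `mixed`, `watson_crick`
#'   (codons read only by Watson-Crick pairing) and `unread`.
#' @export
wobble_codon_classes <- function(anticodons) {
  ac <- toupper(gsub("U", "T", anticodons$anticodon))
  if (any(nchar(ac) != 3) || any(!grepl("^[ACGT]{3}$", ac))) {
    abort("anticodons must be 3-letter DNA strings.")
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  revcomp3 <- function(s) {
    b <- strsplit(s, "")[[1]]
    paste0(comp[b[3]], comp[b[2]], comp[b[1]])
  }
  readings <- purrr::map_dfr(ac, function(a) {
    wc <- revcomp3(a)  # codon positions 1-2 pair anticodon 36-35
    stem <- substr(wc, 1, 2)
    a34 <- substr(a, 1, 1)
    wob <- switch(a34,
                  G = "T", T = "G",
                  A = c("C", "A"),  # inosine
                  C = character(0))
    dplyr::bind_rows(
      tibble::tibble(codon = wc, mode = "wc"),
      if (length(wob) > 0) tibble::tibble(codon = paste0(stem, wob),
                                          mode = "wobble")
    )
  })
  readings <- dplyr::filter(readings, !.data$codon %in% STOP_CODONS)
  modes <- split(readings$mode, readings$codon)
  read <- names(modes)
  has_wc <- vapply(modes, function(m) "wc" %in% m, logical(1))
  has_wob <- vapply(modes, function(m) "wobble" %in% m, logical(1))
  list(
    strict = read[has_wob & !has_wc],
    mixed = read[has_wob & has_wc],
    watson_crick = read[has_wc & !has_wob],
    unread = setdiff(sense_codons(), read)
  )
}
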