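#' Write an annotation as GTF
#'
#' Emits one `transcript` and per-exon `exon` features with `gene_id`,
#' `transcript_id`, `gene_biotype` and `orf_length` attributes (1-based,
#' inclusive coordinates).
#'
#' @param annotation A `cernet_annotation` object (or a transcript tibble
#'   with an `exons` list-column).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(annotation, path) {
  tx <- if (inherits(annotation, "cernet_annotation")) {
    annotation$transcripts
  } else {
    annotation
  }
  rows <- purrr::pmap_dfr(
    tx[, c("transcript_id", "gene_id", "chromosome", "strand", "start",
           "end", "biotype", "orf_length", "exons")],
    function(transcript_id, gene_id, chromosome, strand, start, end,
             biotype, orf_length, exons) {
      bind_rows(
        tibble(chromosome, type = "transcript", start, end, strand,
               gene_id, transcript_id, biotype, orf_length),
        tibble(chromosome, type = "exon", start = exons$start,
               end = exons$end, strand, gene_id, transcript_id, biotype,
               orf_length)
      )
    })
  gr <- GenomicRanges::GRanges(
    seqnames = rows$chromosome,
    ranges = IRanges::IRanges(rows$start, rows$end),
    strand = rows$strand,
    type = rows$type,
    source = "cernet",
    gene_id = rows$gene_id,
    transcript_id = rows$transcript_id,
    gene_biotype = rows$biotype,
    orf_length = as.character(rows$orf_length)
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a transcript annotation from GTF
#'
#' Parses `transcript` and `exon` features (1-based, inclusive) into the
#' transcript tibble used across the package. Mature length is the sum of
#' exon lengths; biotype is taken from `gene_biotype` when present.
#'
#' @param path GTF file.
#' @return Tibble with columns `transcript_id`, `gene_id`, `chromosome`,
#'   `strand`, `start`, `end`, `biotype`, `n_exons`, `length`,
#'   `orf_length`, `exons` (list-column).
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  d <- as_tibble(as.data.frame(gr))
  if (!"gene_biotype" %in% names(d)) d$gene_biotype <- NA_character_
  if (!"orf_length" %in% names(d)) d$orf_length <- NA_character_
  ex <- d |>
    dplyr::filter(.data$type == "exon") |>
    arrange(.data$transcript_id, .data$start) |>
    summarise(
      n_exons = dplyr::n(),
      length = sum(.data$end - .data$start + 1),
      exons = list(tibble(start = start, end = end)),
      .by = "transcript_id"
    )
  d |>
    dplyr::filter(.data$type == "transcript") |>
    transmute(
      transcript_id = .data$transcript_id,
      gene_id = .data$gene_id,
      chromosome = as.character(.data$seqnames),
      strand = as.character(.data$strand),
      start = as.integer(.data$start),
      end = as.integer(.data$end),
      biotype = .data$gene_biotype,
      orf_length = as.integer(.data$orf_length)
    ) |>
    inner_join(ex, by = "transcript_id") |>
    relocate("orf_length", .after = "length")
}

#' Read/write wide expression tables
#'
#' TSV with a `feature_id` first column and one column per sample.
#'
#' @param x Wide tibble (or matrix) to write.
#' @param path File path.
#' @return `read_expression()` returns a wide tibble;
#'   `write_expression()` returns `path` invisibly.
#' @export
write_expression <- function(x, path) {
  if (is.matrix(x)) x <- expr_tibble(x)
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    feature_id = readr::col_character(),
    .default = readr::col_double()), progress = FALSE)
}

#' Read a miRNA-target interaction table
#'
#' Two-column TSV (`mirna_id`, `target_id`), with or without a header.
#'
#' @param path File path.
#' @return Tibble with columns `mirna_id`, `target_id`.
#' @export
read_interactions <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  has_header <- grepl("mirna_id", first, fixed = TRUE)
  readr::read_tsv(path, col_names = if (has_header) TRUE else
                    c("mirna_id", "target_id"),
                  skip = 0, col_types = "cc", progress = FALSE)
}

#' Read coding-potential verdicts
#'
#' Long TSV with columns `transcript_id`, `tool`, `verdict`.
#'
#' @param path File path.
#' @return Tibble in the [simulate_coding_calls()] layout.
#' @export
read_coding_calls <- function(path) {
  readr::read_tsv(path, col_types = "ccc", progress = FALSE)
}

#' Read a term-to-gene annotation map
#'
#' Accepts either a two-column TSV (`term_id`, `gene_id`) or GMT-dialect
#' lines (`term`, description, then genes).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"` or `"gmt"`.
#' @return Tibble with columns `term_id`, `gene_id`.
#' @export
read_term_map <- function(path, format = c("auto", "tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  }
  if (format == "gmt") {
    lines <- readr::read_lines(path)
    purrr::map_dfr(lines, function(l) {
      f <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (length(f) < 3) return(NULL)
      tibble(term_id = f[1], gene_id = f[-(1:2)])
    })
  } else {
    readr::read_tsv(path, col_types = "cc", progress = FALSE)
  }
}

#' Write a simulated dataset to a directory
#'
#' Serializes every component of a [simulate_dataset()] result as the
#' plain-text formats the pipeline consumes: GTF annotation, wide count
#' TSVs, sample sheet, coding-potential calls, interaction tables, and
#' the truth tables (planted triads, per-feature DE truth).
#'
#' @param dataset A `cernet_dataset`.
#' @param dir Destination directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- c(
    annotation = file.path(dir, "annotation.gtf"),
    chrom_sizes = file.path(dir, "chrom_sizes.tsv"),
    mrna = file.path(dir, "mrna_counts.tsv"),
    lncrna = file.path(dir, "lncrna_counts.tsv"),
    mirna = file.path(dir, "mirna_counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    coding_calls = file.path(dir, "coding_calls.tsv"),
    mirna_lncrna = file.path(dir, "mirna_lncrna_interactions.tsv"),
    mirna_mrna = file.path(dir, "mirna_mrna_interactions.tsv"),
    triads = file.path(dir, "planted_triads.tsv"),
    truth = file.path(dir, "expression_truth.tsv")
  )
  write_gtf(dataset$annotation, p[["annotation"]])
  readr::write_tsv(dataset$annotation$chrom_sizes, p[["chrom_sizes"]])
  write_expression(dataset$expression$mrna, p[["mrna"]])
  write_expression(dataset$expression$lncrna, p[["lncrna"]])
  write_expression(dataset$expression$mirna, p[["mirna"]])
  readr::write_tsv(dataset$expression$samples, p[["samples"]])
  readr::write_tsv(dataset$coding_calls, p[["coding_calls"]])
  readr::write_tsv(dataset$interactions$mirna_lncrna, p[["mirna_lncrna"]])
  readr::write_tsv(dataset$interactions$mirna_mrna, p[["mirna_mrna"]])
  readr::write_tsv(dataset$triads, p[["triads"]])
  readr::write_tsv(dataset$expression$truth, p[["truth"]])
  invisible(p)
}
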