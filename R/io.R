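#' Read a BED file of peak calls
#'
#' Reads BED3/BED6 into a tibble of half-open, 0-based intervals, the
#' coordinate convention used throughout the package. Optional columns 4
#' (name) and 5 (score) are captured when present; further columns are
#' ignored. File order is preserved.
#'
#' @param path Path to a tab-separated BED file (3 or more columns).
#' @return A tibble with columns `chrom`, `start`, `end` and, when present in
#'   the file, `name` and `score`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tpk1\t7", tf)
#' read_bed(tf)
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3)) {
    abort(sprintf("BED parse error at line %d: fewer than 3 columns",
                  which(ncols < 3)[1]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end   <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    abort(sprintf("BED parse error at line %d: non-integer coordinates", bad[1]))
  }
  bad <- which(!(start < end) | start < 0)
  if (length(bad) > 0) {
    abort(sprintf("BED parse error at line %d: need 0 <= start < end", bad[1]))
  }
  if (any(!nzchar(chrom))) {
    abort(sprintf("BED parse error at line %d: empty chromosome name",
                  which(!nzchar(chrom))[1]))
  }
  out <- tibble(chrom = chrom, start = start, end = end)
  if (all(ncols >= 4)) {
    out$name <- vapply(fields, `[[`, "", 4L)
  }
  if (all(ncols >= 5)) {
    score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    bad <- which(is.na(score) | score < 0)
    if (length(bad) > 0) {
      abort(sprintf("BED parse error at line %d: score must be a non-negative number",
                    bad[1]))
    }
    out$score <- score
  }
  out
}

#' Write intervals as BED
#'
#' Writes `chrom`, `start`, `end` plus `name` and `score` when present
#' (BED6-style with `.` strand). Deterministic, byte-stable output.
#'
#' @param x A tibble of intervals.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  check_intervals(x, "BED output")
  cols <- sprintf("%s\t%d\t%d", x$chrom, as.integer(x$start), as.integer(x$end))
  has_name <- "name" %in% names(x)
  has_score <- "score" %in% names(x)
  if (has_name || has_score) {
    nm <- if (has_name) x$name else sprintf("region_%d", seq_len(nrow(x)))
    sc <- if (has_score) x$score else rep(0, nrow(x))
    cols <- sprintf("%s\t%s\t%s\t.", cols, nm, format_num(sc))
  }
  writeLines(cols, path)
  invisible(path)
}

#' Read gene models from a GTF annotation
#'
#' Parses records of feature type `"gene"` (falling back to `"transcript"`
#' when a file has no gene records) and converts the GTF 1-based inclusive
#' coordinates to 0-based half-open. The transcription start site (`tss`) is
#' the first transcribed base: `start` on the + strand, `end - 1` on the -
#' strand; `tes` is the opposite end.
#'
#' @param path Path to a GTF file.
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `tss`, `tes`.
#' @export
read_gtf_genes <- function(path) {
  if (!file.exists(path)) abort(sprintf("GTF file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  empty <- tibble(gene_id = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  tss = integer(), tes = integer())
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 9)) {
    abort(sprintf("GTF parse error at line %d: fewer than 9 columns",
                  which(lengths(fields) < 9)[1]))
  }
  feat <- vapply(fields, `[[`, "", 3L)
  keep <- feat == "gene"
  if (!any(keep)) keep <- feat == "transcript"
  if (!any(keep)) return(empty)
  fields <- fields[keep]
  lineno <- which(keep)
  chrom <- vapply(fields, `[[`, "", 1L)
  start1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  end1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
  strand <- vapply(fields, `[[`, "", 7L)
  attrs <- vapply(fields, `[[`, "", 9L)
  bad <- which(is.na(start1) | is.na(end1) | start1 > end1 | start1 < 1)
  if (length(bad) > 0) {
    abort(sprintf("GTF parse error at line %d: invalid coordinates", lineno[bad[1]]))
  }
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad) > 0) {
    abort(sprintf("GTF parse error at line %d: unknown strand %s",
                  lineno[bad[1]], strand[bad[1]]))
  }
  m <- regmatches(attrs, regexec('gene_id[ =]+"?([^";]+)"?', attrs))
  gene_id <- vapply(m, function(g) if (length(g) >= 2) g[2] else NA_character_, "")
  if (anyNA(gene_id)) {
    abort(sprintf("GTF parse error at line %d: missing gene_id attribute",
                  lineno[which(is.na(gene_id))[1]]))
  }
  start0 <- start1 - 1L   # to 0-based half-open
  end0 <- end1
  tibble(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = start0, end = end0,
    tss = ifelse(strand == "+", start0, end0 - 1L),
    tes = ifelse(strand == "+", end0 - 1L, start0)
  )
}

#' Write gene models as GTF
#'
#' Inverse of [read_gtf_genes()]: 0-based half-open spans are written back as
#' 1-based inclusive `gene` records, so read-write-read round-trips exactly.
#'
#' @param genes Tibble of gene models (as returned by [read_gtf_genes()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf_genes <- function(genes, path) {
  lines <- sprintf(
    '%s\tenhancerscope\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
    genes$chrom, as.integer(genes$start) + 1L, as.integer(genes$end),
    genes$strand, genes$gene_id
  )
  writeLines(lines, path)
  invisible(path)
}

#' Construct a signal track
#'
#' A signal track is a tibble of non-overlapping intervals with a
#' non-negative `value` per interval (per-base coverage semantics), sorted by
#' `(chrom, start)`, carrying a `total_mass` attribute used as the
#' per-million denominator in RPM normalization. When `total_mass` is not
#' supplied it defaults to the track's own integral, `sum(value * width)`;
#' supplying the library size (mapped reads) reproduces read-based RPM.
#'
#' @param x Tibble with columns `chrom`, `start`, `end`, `value`.
#' @param total_mass Optional positive denominator overriding the integral.
#' @return A `signal_track` tibble.
#' @export
signal_track <- function(x, total_mass = NULL) {
  check_intervals(x, "signal track")
  if (!"value" %in% names(x)) abort("signal track needs a 'value' column")
  if (any(x$value < 0)) abort("signal track values must be >= 0")
  x <- arrange(x, .data$chrom, .data$start)
  ov <- x |>
    group_by(.data$chrom) |>
    summarise(bad = any(.data$start[-1] < .data$end[-length(.data$end)]),
              .groups = "drop")
  if (any(ov$bad)) {
    abort(sprintf("signal track has overlapping intervals on %s",
                  ov$chrom[ov$bad][1]))
  }
  integral <- sum(x$value * (x$end - x$start))
  mass <- total_mass %||% integral
  if (mass <= 0 && integral > 0) abort("total_mass must be > 0 for a non-empty track")
  out <- as_tibble(x[, c("chrom", "start", "end", "value")])
  attr(out, "total_mass") <- as.numeric(mass)
  class(out) <- c("signal_track", class(out))
  out
}

#' Total mass (RPM denominator) of a signal track
#' @param track A `signal_track`.
#' @return A single number.
#' @export
track_mass <- function(track) {
  m <- attr(track, "total_mass")
  if (is.null(m)) abort("not a signal_track (no total_mass attribute)")
  m
}

#' Read a bedGraph signal track
#'
#' Reads a 4-column bedGraph into a [signal_track()]. Input lines may be
#' unsorted (the reader canonicalizes); overlapping intervals on one
#' chromosome are an error; gaps carry implicit zero signal.
#'
#' @param path Path to a bedGraph file.
#' @param total_mass Optional library size overriding the track integral as
#'   the RPM denominator.
#' @return A `signal_track` tibble.
#' @export
read_bedgraph <- function(path, total_mass = NULL) {
  if (!file.exists(path)) abort(sprintf("bedGraph file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(signal_track(tibble(chrom = character(), start = integer(),
                               end = integer(), value = numeric()),
                        total_mass = total_mass))
  }
  fields <- strsplit(lines, "[ \t]+")
  if (any(lengths(fields) < 4)) {
    abort(sprintf("bedGraph parse error at line %d: fewer than 4 columns",
                  which(lengths(fields) < 4)[1]))
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  value <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  bad <- which(is.na(start) | is.na(end) | is.na(value) | start >= end |
                 start < 0 | value < 0)
  if (length(bad) > 0) {
    abort(sprintf("bedGraph parse error at line %d", bad[1]))
  }
  signal_track(tibble(chrom = vapply(fields, `[[`, "", 1L),
                      start = start, end = end, value = value),
               total_mass = total_mass)
}

#' Write a signal track as bedGraph
#'
#' Values are written with six decimal places, so a write-read round-trip
#' reproduces the track to that precision.
#'
#' @param track A `signal_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  writeLines(sprintf("%s\t%d\t%d\t%.6f", track$chrom,
                     as.integer(track$start), as.integer(track$end),
                     track$value),
             path)
  invisible(path)
}

#' Write a ranked enhancer table with a super-enhancer BED sidecar
#'
#' Writes the full ranked table as TSV (columns `chrom`, `start`, `end`,
#' `n_constituent_peaks`, `signal`, `rank`, `scaled_rank`, `scaled_signal`,
#' `is_super`) and, unless `bed_path = NA`, a BED6 sidecar containing only
#' the super-enhancers (score = signal).
#'
#' @param table A `ranked_enhancers` object from [rank_and_scale()] or
#'   [call_super_enhancers()].
#' @param path Output TSV path.
#' @param bed_path Path for the super-enhancer BED sidecar; default replaces
#'   the TSV extension with `_super.bed`; `NA` suppresses it.
#' @return `path`, invisibly.
#' @export
write_enhancer_table <- function(table, path,
                                 bed_path = sub("\\.[^.]+$", "", path) |>
                                   paste0("_super.bed")) {
  if (is.null(attr(table, "cutoff_rank")) && nrow(table) > 0) {
    abort("table has no cutoff; run find_inflection() first")
  }
  cols <- c("chrom", "start", "end", "n_constituent_peaks", "signal",
            "rank", "scaled_rank", "scaled_signal", "is_super")
  header <- paste(cols, collapse = "\t")
  if (nrow(table) == 0) {
    writeLines(header, path)
  } else {
    rows <- sprintf("%s\t%d\t%d\t%d\t%s\t%d\t%s\t%s\t%s",
                    table$chrom, as.integer(table$start),
                    as.integer(table$end),
                    as.integer(table$n_constituent_peaks),
                    format_num(table$signal), as.integer(table$rank),
                    format_num(table$scaled_rank),
                    format_num(table$scaled_signal),
                    ifelse(table$is_super, "TRUE", "FALSE"))
    writeLines(c(header, rows), path)
  }
  if (!is.na(bed_path)) {
    sup <- table[isTRUE_vec(table$is_super), , drop = FALSE]
    sup <- tibble(chrom = sup$chrom, start = sup$start, end = sup$end,
                  name = sprintf("SE_%d", seq_len(nrow(sup))),
                  score = sup$signal)
    if (nrow(sup) == 0) {
      writeLines(character(), bed_path)
    } else {
      write_bed(sup, bed_path)
    }
  }
  invisible(path)
}

#' Read a gene expression table
#'
#' Reads the long TSV written by [write_expression_table()]: columns
#' `gene_id`, `sample`, `condition`, `fpkm`.
#'
#' @param path Input TSV path.
#' @return A tibble.
#' @export
read_expression_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), sample = readr::col_character(),
    condition = readr::col_character(), fpkm = readr::col_double()))
  if (any(x$fpkm < 0)) abort("FPKM values must be >= 0")
  x
}

#' Write a gene expression table
#' @param expr Long tibble with `gene_id`, `sample`, `condition`, `fpkm`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  write_tsv_stable(expr[, c("gene_id", "sample", "condition", "fpkm")], path)
}

#' Read a histone peptidoform peak-area table
#'
#' Long TSV with columns `peptide_id` (e.g. `"H3 27-40"`), `ptm_combo`
#' (`"+"`-separated mark labels, empty string for the unmodified form),
#' `sample`, `condition`, `area`.
#'
#' @param path Input TSV path.
#' @return A tibble.
#' @export
read_peptidoform_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    peptide_id = readr::col_character(), ptm_combo = readr::col_character(),
    sample = readr::col_character(), condition = readr::col_character(),
    area = readr::col_double()))
  x$ptm_combo[is.na(x$ptm_combo)] <- ""
  if (any(x$area < 0)) abort("peak areas must be >= 0")
  dup <- x |> count(.data$peptide_id, .data$ptm_combo, .data$sample) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate peptidoform record: %s [%s] in sample %s",
                  dup$peptide_id[1], dup$ptm_combo[1], dup$sample[1]))
  }
  x
}

#' Write a histone peptidoform peak-area table
#' @param records Tibble as in [read_peptidoform_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_peptidoform_table <- function(records, path) {
  write_tsv_stable(
    records[, c("peptide_id", "ptm_combo", "sample", "condition", "area")],
    path)
}

# fixed-format numbers: byte-stable output, round-trips to 6 decimals
format_num <- function(x) {
  out <- sprintf("%.6f", x)
  sub("\\.?0+$", "", out)
}

write_tsv_stable <- function(x, path) {
  num <- vapply(x, is.numeric, TRUE) & !vapply(x, is.integer, TRUE)
  x[num] <- lapply(x[num], format_num)
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

isTRUE_vec <- function(x) !is.na(x) & x
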