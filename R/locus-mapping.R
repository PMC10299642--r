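#' 1-based inclusive genomic interval(s)
#'
#' Chromosome names are normalized by stripping a leading `"chr"` prefix so
#' that UCSC- and Ensembl-style names compare equal.
#'
#' @param chrom Chromosome name(s).
#' @param start,end 1-based inclusive coordinates (`start <= end`, both
#'   >= 1).
#' @param label Interval label(s) (gene or locus name).
#' @return Data.frame of class `genomic_interval` with columns `label`,
#'   `chrom`, `start`, `end`.
#' @export
genomic_interval <- function(chrom, start, end, label = NA_character_) {
  chrom <- sub("^chr", "", as.character(chrom))
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(!is.finite(start)) || any(!is.finite(end))) {
    stop("interval coordinates must be finite numbers", call. = FALSE)
  }
  if (any(start < 1) || any(end < 1)) {
    stop("1-based coordinates must be >= 1", call. = FALSE)
  }
  if (any(start > end)) {
    bad <- which(start > end)[1]
    stop(sprintf("interval %d has start > end (%g > %g)", bad, start[bad], end[bad]),
         call. = FALSE)
  }
  structure(data.frame(label = as.character(label), chrom = chrom,
                       start = start, end = end, stringsAsFactors = FALSE),
            class = c("genomic_interval", "data.frame"))
}

.one_interval <- function(x) {
  stopifnot(inherits(x, "genomic_interval") || is.data.frame(x), nrow(x) == 1L)
  x
}

#' Gap between two same-chromosome intervals in base pairs
#'
#' Plain boundary arithmetic with no off-by-one adjustment: 0 when the
#' intervals overlap or share a coordinate, otherwise the positive
#' difference between the nearest boundaries (`b.start - a.end` or
#' `a.start - b.end`). This matches how megabase distances between a gene
#' and the nearest critical-region marker are conventionally quoted.
#' Symmetric in its arguments.
#'
#' @param a,b Single-row [genomic_interval()] objects.
#' @return Gap in bp (0 for overlap). Errors if the chromosomes differ;
#'   use [assess_candidacy()] for an `"incomparable"` status instead.
#' @export
interval_gap <- function(a, b) {
  a <- .one_interval(a); b <- .one_interval(b)
  if (a$chrom != b$chrom) {
    stop(sprintf("intervals lie on different chromosomes (%s vs %s)",
                 a$chrom, b$chrom), call. = FALSE)
  }
  max(0, b$start - a$end, a$start - b$end)
}

#' Place a gene relative to a marker-defined critical region
#'
#' Candidacy call for a gene against a deafness locus: `"inside"` when the
#' gene lies fully within the critical region, `"overlapping"` for partial
#' overlap, `"outside"` with the boundary gap otherwise, and
#' `"incomparable"` when the two intervals are on different chromosomes.
#'
#' @param gene,locus Single-row [genomic_interval()] objects.
#' @return A `candidacy_report` data.frame row: `gene`, `locus`, `status`,
#'   `gap_bp`, `gap_mb` (gap in megabases rounded to 1 decimal).
#' @export
assess_candidacy <- function(gene, locus) {
  gene <- .one_interval(gene); locus <- .one_interval(locus)
  if (gene$chrom != locus$chrom) {
    status <- "incomparable"; gap <- NA_real_
  } else {
    gap <- interval_gap(gene, locus)
    status <- if (gap > 0) "outside"
      else if (gene$start >= locus$start && gene$end <= locus$end) "inside"
      else "overlapping"
    if (status != "outside") gap <- 0
  }
  structure(data.frame(gene = gene$label, locus = locus$label,
                       status = status, gap_bp = gap,
                       gap_mb = round(gap / 1e6, 1),
                       stringsAsFactors = FALSE),
            class = c("candidacy_report", "data.frame"))
}

#' Read genomic intervals from BED or label/coordinate TSV
#'
#' `dialect = "bed"` reads standard BED (0-based half-open) through
#' rtracklayer, converting to 1-based inclusive coordinates.
#' `dialect = "table1_tsv"` reads a two-column tab-separated file with a
#' header, column 1 the label and column 2 a coordinate string
#' `chrom:start-end` already 1-based inclusive (`"n/a"` rows are skipped).
#'
#' @param path File path.
#' @param dialect `"table1_tsv"` or `"bed"`.
#' @return A multi-row [genomic_interval()].
#' @export
read_intervals <- function(path, dialect = c("table1_tsv", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    lab <- if (!is.null(gr$name)) as.character(gr$name) else NA_character_
    genomic_interval(as.character(GenomeInfoDb::seqnames(gr)),
                     BiocGenerics::start(gr), BiocGenerics::end(gr), lab)
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    df <- df[df[[2]] != "n/a", , drop = FALSE]
    parsed <- parse_coord(df[[2]])
    out <- genomic_interval(parsed$chrom, parsed$start, parsed$end, df[[1]])
    bad <- which(out$start > out$end)
    if (length(bad)) {
      stop(sprintf("line %d: start > end after parsing", bad[1] + 1L),
           call. = FALSE)
    }
    out
  }
}

#' Parse `chrom:start-end` coordinate strings
#'
#' @param x Character vector like `"19:463346-474880"`.
#' @return Data.frame with `chrom`, `start`, `end`.
#' @export
parse_coord <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)[-:]([0-9]+)$", x))
  if (any(vapply(m, length, 1L) != 4L)) {
    stop("coordinates must look like 'chrom:start-end'", call. = FALSE)
  }
  data.frame(chrom = vapply(m, `[[`, "", 2),
             start = as.numeric(vapply(m, `[[`, "", 3)),
             end = as.numeric(vapply(m, `[[`, "", 4)),
             stringsAsFactors = FALSE)
}

#' Write intervals as label/coordinate TSV
#'
#' Inverse of `read_intervals(dialect = "table1_tsv")`; round trips are
#' lossless.
#'
#' @param intervals A [genomic_interval()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  df <- data.frame(label = intervals$label,
                   coordinates = sprintf("%s:%d-%d", intervals$chrom,
                                         as.integer(intervals$start),
                                         as.integer(intervals$end)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Candidacy report for a packaged gene/locus pairing table
#'
#' Evaluates every gene/locus pairing of a table like the packaged
#' deafness-candidacy fixture (`system.file("extdata",
#' "deafness_candidacy.tsv", package = "kinoprofile")`): columns `gene`,
#' `gene_coordinates`, `locus`, `locus_coordinates`, where a locus of
#' `"n/a"` records that no deafness locus is proposed for that gene and
#' yields a `status` of `"n/a"`.
#'
#' @param path TSV path; defaults to the packaged fixture of human
#'   gene/deafness-locus coordinate pairs (GRCh38).
#' @return Data.frame with one row per pairing: `gene`, `locus`, `status`,
#'   `gap_bp`, `gap_mb`.
#' @export
candidacy_table <- function(path = system.file("extdata", "deafness_candidacy.tsv",
                                               package = "kinoprofile")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    if (df$locus[i] == "n/a" || df$locus_coordinates[i] == "n/a") {
      return(data.frame(gene = df$gene[i], locus = "n/a", status = "n/a",
                        gap_bp = NA_real_, gap_mb = NA_real_,
                        stringsAsFactors = FALSE))
    }
    g <- parse_coord(df$gene_coordinates[i])
    l <- parse_coord(df$locus_coordinates[i])
    assess_candidacy(genomic_interval(g$chrom, g$start, g$end, df$gene[i]),
                     genomic_interval(l$chrom, l$start, l$end, df$locus[i]))
  })
  do.call(rbind, rows)
}
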