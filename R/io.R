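#' Read a per-CpG count table
#'
#' Supported dialects:
#' * `bismark_cov`: `chrom  start  end  pct  count_methylated
#'   count_unmethylated`, 1-based inclusive coordinates (the bismark
#'   coverage format);
#' * `bedgraph_pair`: the same six columns with 0-based half-open
#'   coordinates (bismark's zero-based bedGraph variant);
#' * `tsv`: headered `chrom  pos  nc  n` with 0-based positions.
#'
#' Coordinates are normalised to the package-internal 0-based convention;
#' counts must be non-negative integers with `nc <= n`.
#'
#' @param path File path.
#' @param dialect One of `"bismark_cov"`, `"bedgraph_pair"`, `"tsv"`.
#'
#' @return `data.frame` with columns `chrom`, `pos` (0-based), `nc`
#'   (retained cytosines), `n` (coverage).
#' @export
read_cpg_counts <- function(path, dialect = c("bismark_cov", "bedgraph_pair",
                                              "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- dialect == "tsv"
  raw <- tryCatch(
    read.table(path, sep = "\t", header = header, stringsAsFactors = FALSE,
               colClasses = NA, comment.char = "#"),
    error = function(e) NULL
  )
  if (is.null(raw) || !nrow(raw)) {
    warning("no records read from ", path)
    return(data.frame(chrom = character(0), pos = integer(0),
                      nc = integer(0), n = integer(0),
                      stringsAsFactors = FALSE))
  }
  if (dialect == "tsv") {
    need <- c("chrom", "pos", "nc", "n")
    if (!all(need %in% names(raw))) {
      stop("tsv dialect requires columns: ", paste(need, collapse = ", "))
    }
    out <- data.frame(chrom = as.character(raw$chrom),
                      pos = as.integer(raw$pos),
                      nc = as.integer(raw$nc), n = as.integer(raw$n),
                      stringsAsFactors = FALSE)
  } else {
    if (ncol(raw) < 6L) stop("expected 6 columns in ", dialect, " input")
    meth <- as.integer(raw[[5L]])
    unmeth <- as.integer(raw[[6L]])
    pos <- as.integer(raw[[2L]]) - if (dialect == "bismark_cov") 1L else 0L
    out <- data.frame(chrom = as.character(raw[[1L]]), pos = pos,
                      nc = meth, n = meth + unmeth,
                      stringsAsFactors = FALSE)
  }
  line_off <- if (header) 1L else 0L
  bad <- which(is.na(out$nc) | is.na(out$n) | out$nc < 0L | out$n < 0L |
                 out$nc > out$n | is.na(out$pos) | out$pos < 0L)
  if (length(bad)) {
    stop("invalid count record at line ", bad[1L] + line_off, " of ", path)
  }
  if (anyDuplicated(paste(out$chrom, out$pos))) {
    stop("duplicate (chrom, pos) records in ", path)
  }
  out
}

#' Write a per-CpG count table
#'
#' Inverse of [read_cpg_counts()]; `bismark_cov` writes 1-based inclusive
#' coordinates with a percent-methylation column, `tsv` writes the headered
#' internal 0-based layout.
#'
#' @param counts Count table (`chrom`, `pos`, `nc`, `n`).
#' @param path Output path.
#' @param dialect `"bismark_cov"`, `"bedgraph_pair"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_cpg_counts <- function(counts, path, dialect = c("bismark_cov",
                                                       "bedgraph_pair",
                                                       "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    write.table(counts[, c("chrom", "pos", "nc", "n")], path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    start <- counts$pos + if (dialect == "bismark_cov") 1L else 0L
    end <- if (dialect == "bismark_cov") start else start + 1L
    pct <- ifelse(counts$n > 0, 100 * counts$nc / counts$n, 0)
    write.table(
      data.frame(counts$chrom, start, end, pct, counts$nc,
                 counts$n - counts$nc),
      path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
  }
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' BED3 or BED4+ input; column 4, when present, becomes the feature label.
#' Coordinates are BED-native (0-based half-open) and are kept as-is.
#' Overlapping intervals are preserved, never merged.
#'
#' @param path File path.
#' @return Interval table (`chrom`, `start`, `end`, `name`).
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < 3L) stop("BED input needs at least 3 columns")
  start <- suppressWarnings(as.integer(raw[[2L]]))
  end <- suppressWarnings(as.integer(raw[[3L]]))
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad)) {
    stop("malformed BED interval at line ", bad[1L], " of ", path)
  }
  genomic_intervals(raw[[1L]], start, end,
                    if (ncol(raw) >= 4L) as.character(raw[[4L]]) else
                      NA_character_)
}
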