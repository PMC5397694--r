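#' Construct a table of genomic intervals
#'
#' Intervals use the BED convention throughout the package: 0-based start,
#' half-open `[start, end)`.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; `start` 0-based inclusive, `end`
#'   exclusive. Must satisfy `start < end`.
#' @param name Optional feature labels (recycled).
#'
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`.
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.integer(start), n)
  end <- rep_len(as.integer(end), n)
  if (any(is.na(chrom)) || any(!nzchar(chrom))) {
    stop("chromosome names must be non-empty")
  }
  if (any(is.na(start)) || any(is.na(end)) || any(start < 0L)) {
    stop("interval coordinates must be non-negative integers")
  }
  if (any(start >= end)) {
    bad <- which(start >= end)[1L]
    stop("interval start must be < end (record ", bad, ")")
  }
  data.frame(
    chrom = chrom, start = start, end = end,
    name = rep_len(as.character(name), n),
    stringsAsFactors = FALSE
  )
}

# Overlap join between point positions (0-based) and intervals.
# Returns data.frame(point = index into pos, region = index into regions).
overlap_points_regions <- function(chrom_p, pos, regions) {
  out_p <- integer(0)
  out_r <- integer(0)
  for (ch in unique(regions$chrom)) {
    ip <- which(chrom_p == ch)
    ir <- which(regions$chrom == ch)
    if (!length(ip) || !length(ir)) next
    hits <- findOverlaps(
      IRanges(pos[ip] + 1L, pos[ip] + 1L),
      IRanges(regions$start[ir] + 1L, regions$end[ir])
    )
    out_p <- c(out_p, ip[queryHits(hits)])
    out_r <- c(out_r, ir[subjectHits(hits)])
  }
  data.frame(point = out_p, region = out_r)
}

# Merge overlapping/adjacent intervals within each chromosome.
merge_intervals <- function(regions) {
  pieces <- lapply(split(seq_len(nrow(regions)), regions$chrom), function(idx) {
    red <- reduce(IRanges(regions$start[idx] + 1L, regions$end[idx]))
    data.frame(
      chrom = regions$chrom[idx[1L]],
      start = start(red) - 1L, end = end(red),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Complement of intervals within [0, chrom_len) for a single chromosome.
complement_intervals <- function(starts, ends, chrom_len) {
  if (!length(starts)) {
    return(data.frame(start = 0L, end = as.integer(chrom_len)))
  }
  o <- order(starts)
  starts <- starts[o]
  ends <- ends[o]
  gap_start <- c(0L, ends)
  gap_end <- c(starts, as.integer(chrom_len))
  keep <- gap_start < gap_end
  data.frame(start = gap_start[keep], end = gap_end[keep])
}

#' Derive CpG-island shores
#'
#' Shores are the flanking regions on either side of a CpG island (CGI),
#' `flank` bases wide, clipped at position 0 and at the chromosome end when
#' known, and with any bases falling inside another CGI removed (shores are
#' by definition non-island sequence).
#'
#' @param cgis Interval table of CpG islands (see [genomic_intervals()]).
#' @param flank Shore width in bases on each side (default 2000).
#' @param chrom_sizes Optional named vector of chromosome lengths used to
#'   clip right shores.
#'
#' @return Interval table of shores, labelled `"shore"`. Shores never
#'   intersect any input CGI and total at most `2 * flank` bases per island.
#' @export
cgi_shores <- function(cgis, flank = 2000L, chrom_sizes = NULL) {
  flank <- as.integer(flank)
  stopifnot(flank > 0L)
  left <- data.frame(
    chrom = cgis$chrom,
    start = pmax(0L, cgis$start - flank),
    end = cgis$start, stringsAsFactors = FALSE
  )
  right <- data.frame(chrom = cgis$chrom, start = cgis$end,
                      end = cgis$end + flank, stringsAsFactors = FALSE)
  if (!is.null(chrom_sizes)) {
    lim <- as.integer(chrom_sizes[right$chrom])
    lim[is.na(lim)] <- .Machine$integer.max
    right$end <- pmin(right$end, lim)
  }
  raw <- rbind(left, right)
  raw <- raw[raw$start < raw$end, , drop = FALSE]
  # subtract islands chromosome-wise
  pieces <- lapply(unique(raw$chrom), function(ch) {
    sh <- IRanges(raw$start[raw$chrom == ch] + 1L, raw$end[raw$chrom == ch])
    isl <- cgis[cgis$chrom == ch, , drop = FALSE]
    kept <- IRanges::setdiff(reduce(sh), IRanges(isl$start + 1L, isl$end))
    if (!length(kept)) return(NULL)
    data.frame(chrom = ch, start = start(kept) - 1L, end = end(kept),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    return(genomic_intervals(character(0), integer(0), integer(1))[0, ])
  }
  out$name <- "shore"
  rownames(out) <- NULL
  out
}

#' Tile a chromosome into fixed-width bins
#'
#' @param chrom_len Chromosome length in bases.
#' @param tile_width Bin width (default 300, the standard hMeDIP tiling).
#' @param chrom Chromosome name.
#'
#' @return Interval table covering `[0, chrom_len)`; the last tile may be
#'   shorter.
#' @export
tile_genome <- function(chrom_len, tile_width = 300L, chrom = "chr1") {
  chrom_len <- as.integer(chrom_len)
  tile_width <- as.integer(tile_width)
  stopifnot(chrom_len > 0L, tile_width > 0L)
  starts <- seq.int(0L, chrom_len - 1L, by = tile_width)
  data.frame(
    chrom = chrom, start = starts,
    end = pmin(starts + tile_width, chrom_len),
    stringsAsFactors = FALSE
  )
}
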