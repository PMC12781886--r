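#' Strand-specific per-base 3'-end coverage track
#'
#' Single-nucleotide counts of nascent-transcript 3' ends over a genomic
#' window, the unit of NET-seq style analysis. Coordinates are 0-based
#' half-open internally.
#'
#' @param start 0-based start of the window.
#' @param counts Non-negative per-base counts (window length =
#'   `length(counts)`).
#' @param seqname Sequence (chromosome) name.
#' @param strand `"+"` or `"-"`.
#' @param label Optional library label.
#' @return Data frame `pos`, `count` of class `coverage_track` with
#'   attributes `seqname`, `strand`, `label`.
#' @export
coverage_track <- function(start, counts, seqname = "Chr1", strand = "+",
                           label = NULL) {
  stopifnot(length(counts) >= 1L, all(counts >= 0),
            strand %in% c("+", "-"))
  structure(
    data.frame(pos = seq.int(start, start + length(counts) - 1L),
               count = as.numeric(counts)),
    seqname = seqname, strand = strand, label = label,
    class = c("coverage_track", "data.frame")
  )
}

track_strand <- function(track) attr(track, "strand")

#' Gene annotation windows for termination-index analysis
#'
#' Defines, in 0-based half-open coordinates, the analysed gene span, the
#' termination window around the first major polyadenylation site (PAS),
#' the remaining gene body (span minus termination window), splice-site
#' positions for splice-intermediate filtering, and reference-gene totals
#' used for normalization. The termination window covers transcript
#' offsets `[-upstream, +downstream)` around the PAS and is flipped to
#' genomic coordinates for minus-strand genes.
#'
#' @param start,end Gene span (TSS to 3'UTR end for a plus-strand gene),
#'   0-based half-open.
#' @param pas 0-based position of the first major PAS; must lie within
#'   the gene span, and the derived termination window must too.
#' @param strand `"+"` or `"-"`.
#' @param seqname Sequence name.
#' @param splice_sites_5,splice_sites_3 0-based positions of annotated 5'
#'   and 3' splice sites.
#' @param term_upstream,term_downstream Window extent around the PAS in
#'   transcript orientation (defaults 150 and 400 nt).
#' @return An object of class `gene_windows`.
#' @export
gene_windows <- function(start, end, pas, strand = "+", seqname = "Chr1",
                         splice_sites_5 = integer(), splice_sites_3 = integer(),
                         term_upstream = 150L, term_downstream = 400L) {
  stopifnot(end > start, strand %in% c("+", "-"),
            term_upstream >= 0L, term_downstream >= 1L)
  if (pas < start || pas >= end) {
    stop("PAS must lie within the gene span", call. = FALSE)
  }
  if (strand == "+") {
    term_start <- pas - term_upstream
    term_end <- pas + term_downstream
  } else {
    term_start <- pas - term_downstream + 1L
    term_end <- pas + term_upstream + 1L
  }
  if (term_start < start || term_end > end) {
    stop("termination window extends outside the gene span", call. = FALSE)
  }
  structure(
    list(start = start, end = end, pas = pas, strand = strand,
         seqname = seqname, term_start = term_start, term_end = term_end,
         splice_sites_5 = splice_sites_5, splice_sites_3 = splice_sites_3),
    class = "gene_windows"
  )
}

#' Normalize a coverage track to reference-gene totals
#'
#' Divides every count by the geometric mean of the total counts over the
#' reference genes (e.g. ACT7 and UBC21), putting libraries of different
#' depth on a common scale. A single reference total degenerates to
#' division by that total. All within-track count ratios are preserved.
#'
#' @param track A [coverage_track()].
#' @param ref_totals Strictly positive total counts over each
#'   reference-gene span.
#' @return The normalized track.
#' @export
normalize_track <- function(track, ref_totals) {
  stopifnot(inherits(track, "coverage_track"), length(ref_totals) >= 1L)
  if (any(ref_totals <= 0)) {
    stop("reference totals must all be strictly positive", call. = FALSE)
  }
  divisor <- exp(mean(log(ref_totals)))
  track$count <- track$count / divisor
  track
}

#' Remove read 3' ends at splice sites
#'
#' Read 3' ends coinciding with annotated 5' or 3' splice-site positions
#' on the gene's strand likely represent co-transcriptional splicing
#' intermediates rather than PolII positions, and are removed before
#' coverage analysis. Matching is within `width` nt of a site (default 1,
#' i.e. exact single-base coincidence); only reads on the annotation's
#' strand are filtered. The operation is idempotent.
#'
#' @param ends Integer vector of 0-based read 3'-end positions, or a data
#'   frame with columns `pos` and `strand`.
#' @param windows A [gene_windows()] carrying the splice-site annotation.
#' @param width Match width in nt (positions with
#'   `|pos - site| < width` are removed).
#' @return Filtered positions (same shape as the input) with attribute
#'   `n_removed`.
#' @export
filter_splice_intermediates <- function(ends, windows, width = 1L) {
  stopifnot(inherits(windows, "gene_windows"), width >= 1L)
  sites <- c(windows$splice_sites_5, windows$splice_sites_3)
  df <- if (is.data.frame(ends)) ends else
    data.frame(pos = ends, strand = windows$strand)
  at_site <- if (length(sites) == 0L) rep(FALSE, nrow(df)) else
    vapply(df$pos, function(p) any(abs(p - sites) < width), logical(1))
  drop <- at_site & df$strand == windows$strand
  out <- if (is.data.frame(ends)) df[!drop, , drop = FALSE] else
    df$pos[!drop]
  attr(out, "n_removed") <- sum(drop)
  out
}

sum_window <- function(track, from, to) {
  sum(track$count[track$pos >= from & track$pos < to])
}

#' PolII termination index
#'
#' Ratio of 3'-end counts in the termination window around the first
#' major PAS to the counts over the remaining gene body. Under a
#' steady-state piecewise-density picture (density proportional to `F/v`
#' in each region, with the termination-region speed unchanged between
#' conditions) the TI is proportional to the gene-body speed, making its
#' fold change a readout of the PolII elongation-rate fold change. The TI
#' is invariant to normalization and uniform depth scaling. Antisense
#' reads never contribute: the track strand must match the annotation.
#'
#' @param track A [coverage_track()] on the gene's strand.
#' @param windows A [gene_windows()].
#' @return Scalar TI; `NA` with a warning if the gene-body counts are
#'   zero (undefined).
#' @export
termination_index <- function(track, windows) {
  stopifnot(inherits(track, "coverage_track"), inherits(windows, "gene_windows"))
  if (track_strand(track) != windows$strand) {
    stop("track strand does not match the gene annotation; ",
         "antisense signal must not enter the TI", call. = FALSE)
  }
  term <- sum_window(track, windows$term_start, windows$term_end)
  body <- sum_window(track, windows$start, windows$end) - term
  if (body <= 0) {
    warning("zero gene-body counts: termination index undefined",
            call. = FALSE)
    return(NA_real_)
  }
  term / body
}

#' Termination indices and speed fold changes across libraries
#'
#' Computes the per-library TI, per-condition mean and s.d. across
#' replicates, and the gene-body elongation-rate fold change of each
#' condition relative to a reference condition.
#'
#' @param tracks List of [coverage_track()] objects.
#' @param windows A [gene_windows()].
#' @param conditions Condition label per track.
#' @param reference Reference condition label (default first).
#' @return List with `ti` (per-library data frame) and `by_condition`
#'   (data frame `condition`, `mean_ti`, `sd_ti`, `n`, `speed_fc`).
#' @export
ti_summary <- function(tracks, windows, conditions,
                       reference = conditions[1]) {
  stopifnot(length(tracks) == length(conditions))
  ti <- vapply(tracks, termination_index, numeric(1), windows = windows)
  per <- data.frame(condition = conditions, ti = ti)
  agg <- do.call(rbind, lapply(split(per, per$condition), function(d) {
    data.frame(condition = d$condition[1], mean_ti = mean(d$ti),
               sd_ti = stats::sd(d$ti), n = nrow(d))
  }))
  rownames(agg) <- NULL
  if (!reference %in% agg$condition) {
    stop("reference condition not present", call. = FALSE)
  }
  ref_ti <- agg$mean_ti[agg$condition == reference]
  agg$speed_fc <- speed_fc(agg$mean_ti, ref_ti)
  agg <- agg[order(match(agg$condition, unique(conditions))), ]
  rownames(agg) <- NULL
  list(ti = per, by_condition = agg)
}

#' Gene-body elongation-rate fold change from termination indices
#'
#' Under the piecewise steady-state density model (initiation and
#' termination-window speed unchanged), the gene-body speed fold change
#' between two conditions equals the ratio of their termination indices.
#'
#' @param ti_condition,ti_reference Termination indices (reference must
#'   be non-zero).
#' @return `ti_condition / ti_reference`, vectorized over the first
#'   argument.
#' @export
speed_fc <- function(ti_condition, ti_reference) {
  if (any(is.na(ti_condition)) || is.na(ti_reference)) {
    stop("termination indices must be defined", call. = FALSE)
  }
  if (ti_reference <= 0) stop("reference TI must be > 0", call. = FALSE)
  ti_condition / ti_reference
}

#' Polycomb spread fraction implied by a speed fold change
#'
#' Convenience wrapper around [spread_fraction()] returning the implied
#' fraction of gene copies in the H3K27me3 spread state together with a
#' readable label.
#'
#' @inheritParams spread_fraction
#' @return List with `fraction` and `label`.
#' @export
spread_fraction_report <- function(speed_fc, silenced_speed_ratio = 0.1) {
  p <- spread_fraction(speed_fc, silenced_speed_ratio)
  list(fraction = p,
       label = sprintf(
         "speed FC %.2g with %.2g-fold slower silenced state => ~%.1f of copies in the spread state",
         speed_fc, 1 / silenced_speed_ratio, round(p, 1)))
}

#' Read a strand-specific bedGraph file into a coverage track
#'
#' Imports a 4-column bedGraph (0-based half-open) and expands it to
#' per-base counts over the requested window. bedGraph itself carries no
#' strand; the strand of the library is supplied by the caller.
#'
#' @param path bedGraph file.
#' @param seqname Sequence to extract.
#' @param from,to 0-based half-open window; defaults to the covered span.
#' @param strand Library strand.
#' @param label Optional library label.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, seqname = NULL, from = NULL, to = NULL,
                          strand = "+", label = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (is.null(seqname)) seqname <- as.character(GenomicRanges::seqnames(gr)[1])
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == seqname]
  if (length(gr) == 0L) stop("no intervals on ", seqname, call. = FALSE)
  st0 <- GenomicRanges::start(gr) - 1L   # to 0-based
  en0 <- GenomicRanges::end(gr)
  if (is.null(from)) from <- min(st0)
  if (is.null(to)) to <- max(en0)
  counts <- numeric(to - from)
  for (k in seq_along(gr)) {
    a <- max(st0[k], from)
    b <- min(en0[k], to)
    if (b > a) counts[(a - from + 1L):(b - from)] <- gr$score[k]
  }
  coverage_track(from, counts, seqname = seqname, strand = strand,
                 label = label)
}

#' Write a coverage track as bedGraph
#'
#' Collapses runs of equal counts and exports 0-based half-open
#' intervals; zero-count runs are omitted.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  r <- rle(track$count)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  gr <- GenomicRanges::GRanges(
    seqnames = attr(track, "seqname"),
    ranges = IRanges::IRanges(start = track$pos[starts[keep]] + 1L,
                              end = track$pos[ends[keep]] + 1L),
    score = r$values[keep]
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write a gene model as GFF3
#'
#' Emits the gene span, its exons (from which splice sites are
#' recoverable) and the first major PAS as a `polyA_site` feature, in
#' 1-based closed GFF3 coordinates.
#'
#' @param windows A [gene_windows()].
#' @param path Output path.
#' @param gene_id Feature identifier.
#' @param exons Optional data frame `start`, `end` (0-based half-open) of
#'   exons; if omitted, exon boundaries are reconstructed from the
#'   annotated splice sites.
#' @return `path`, invisibly.
#' @export
write_gene_gff3 <- function(windows, path, gene_id = "gene1", exons = NULL) {
  stopifnot(inherits(windows, "gene_windows"))
  if (is.null(exons)) exons <- exons_from_splice_sites(windows)
  feats <- data.frame(
    start0 = c(windows$start, exons$start, windows$pas),
    end0 = c(windows$end, exons$end, windows$pas + 1L),
    type = c("gene", rep("exon", nrow(exons)), "polyA_site"),
    id = c(gene_id, sprintf("%s.exon%d", gene_id, seq_len(nrow(exons))),
           paste0(gene_id, ".pas1"))
  )
  gr <- GenomicRanges::GRanges(
    seqnames = windows$seqname,
    ranges = IRanges::IRanges(start = feats$start0 + 1L, end = feats$end0),
    strand = windows$strand
  )
  gr$type <- feats$type
  gr$ID <- feats$id
  gr$Parent <- c(NA, rep(gene_id, nrow(feats) - 1L))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

exons_from_splice_sites <- function(windows) {
  d5 <- sort(windows$splice_sites_5)
  a3 <- sort(windows$splice_sites_3)
  if (length(d5) != length(a3)) {
    stop("unequal numbers of 5' and 3' splice sites", call. = FALSE)
  }
  if (windows$strand == "+") {
    data.frame(start = c(windows$start, a3 + 1L), end = c(d5, windows$end))
  } else {
    data.frame(start = c(windows$start, d5 + 1L), end = c(a3, windows$end))
  }
}

#' Read a gene model from GFF3 into analysis windows
#'
#' Reads a GFF3 gene model (1-based closed, converted to 0-based
#' half-open internally): the `gene` feature gives the span, a
#' `polyA_site` feature gives the PAS, and exon boundaries give the
#' splice sites (a plus-strand exon end is a 5' splice site, the next
#' exon start a 3' splice site).
#'
#' @param path GFF3 file.
#' @param gene_id Optional gene `ID` to select if several are present.
#' @inheritParams gene_windows
#' @return A [gene_windows()].
#' @export
read_gene_windows <- function(path, gene_id = NULL,
                              term_upstream = 150L, term_downstream = 400L) {
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  if (!is.null(gene_id)) genes <- genes[genes$ID == gene_id]
  if (length(genes) == 0L) stop("no gene feature found", call. = FALSE)
  g <- genes[1]
  strand <- as.character(GenomicRanges::strand(g))
  pas <- gr[gr$type == "polyA_site"]
  if (length(pas) == 0L) stop("no polyA_site feature found", call. = FALSE)
  exons <- gr[gr$type == "exon"]
  exons <- exons[order(GenomicRanges::start(exons))]
  s0 <- GenomicRanges::start(exons) - 1L
  e0 <- GenomicRanges::end(exons)
  n <- length(exons)
  if (n >= 2L) {
    if (strand == "+") {
      ss5 <- e0[-n]          # end of exon i = donor
      ss3 <- s0[-1L] - 1L    # last intronic base before next exon
    } else {
      ss5 <- s0[-1L] - 1L
      ss3 <- e0[-n]
    }
  } else {
    ss5 <- ss3 <- integer()
  }
  gene_windows(
    start = GenomicRanges::start(g) - 1L, end = GenomicRanges::end(g),
    pas = GenomicRanges::start(pas)[1] - 1L, strand = strand,
    seqname = as.character(GenomicRanges::seqnames(g)),
    splice_sites_5 = ss5, splice_sites_3 = ss3,
    term_upstream = term_upstream, term_downstream = term_downstream
  )
}
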