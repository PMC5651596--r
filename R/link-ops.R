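#' Partition links by CTCF motif interruption
#'
#' A link is "interrupted" when at least one CTCF motif lies entirely within
#' the open gap between its two anchors — evidence that the anchors sit in
#' different chromatin loops. Motifs overlapping an anchor itself do not
#' interrupt: the criterion is loop-boundary crossing *between* the
#' elements.
#'
#' @param links A link table.
#' @param ctcf_motifs Interval tibble of CTCF motif positions.
#' @return List with elements `uninterrupted` and `interrupted`, a partition
#'   of the input.
#' @export
filter_ctcf_uninterrupted <- function(links, ctcf_motifs) {
  interrupted <- logical(nrow(links))
  for (cn in unique(links$chrom)) {
    idx <- which(links$chrom == cn)
    m <- ctcf_motifs[ctcf_motifs$chrom == cn, ]
    if (nrow(m) == 0) next
    ms <- sort(m$start)
    # motif [s, e) inside the open gap [end_a, start_b): s >= end_a, e <= start_b
    me <- m$end[order(m$start)]
    for (j in idx) {
      k <- which(ms >= links$end_a[j] & me <= links$start_b[j])
      interrupted[j] <- length(k) > 0
    }
  }
  list(uninterrupted = links[!interrupted, ], interrupted = links[interrupted, ])
}

#' Keep the most significant link per target
#'
#' For each gene/CpG target keep only the link with the smallest score
#' (score read as a p value). Ties go to the shorter link, then to the
#' leftmost anchor, so the choice is deterministic. Links without a target
#' id are dropped with a warning.
#'
#' @param links A link table with `target_id` and `score`.
#' @return The reduced link table, one row per target.
#' @export
select_best_per_target <- function(links) {
  no_target <- is.na(links$target_id)
  if (any(no_target)) {
    warn(paste0("dropped ", sum(no_target), " link(s) without target_id"))
    links <- links[!no_target, ]
  }
  links |>
    dplyr::arrange(.data$score, .data$distance, .data$start_a) |>
    dplyr::distinct(.data$target_id, .keep_all = TRUE)
}

#' Prune links re-using the same genomic region
#'
#' Greedy pruning by significance: links are visited in ascending score
#' order and accepted unless either anchor midpoint lies within
#' `exclusion_radius` of an already-accepted anchor on the same chromosome.
#' Removes multiple counts of one SNP or one promoter across many links.
#'
#' @param links A link table (score read as p value; smaller = better).
#' @param exclusion_radius Radius in bp (default 1000).
#' @return The accepted subset; no two accepted anchors lie within the
#'   radius of each other.
#' @export
prune_overlapping <- function(links, exclusion_radius = 1000) {
  ord <- order(links$score, links$distance, links$start_a)
  keep <- logical(nrow(links))
  accepted <- list()
  mid_a <- (links$start_a + links$end_a) / 2
  mid_b <- (links$start_b + links$end_b) / 2
  for (j in ord) {
    cn <- links$chrom[j]
    acc <- accepted[[cn]]
    if (is.null(acc) ||
        (min(abs(c(acc - mid_a[j], acc - mid_b[j]))) > exclusion_radius)) {
      keep[j] <- TRUE
      accepted[[cn]] <- c(acc, mid_a[j], mid_b[j])
    }
  }
  links[sort(which(keep)), ]
}

#' Threshold a link set by score
#'
#' @param links A link table.
#' @param mode `"top_fraction"` keeps the `ceiling(value * n)` links with
#'   the highest scores (e.g. top 10 percent of Hi-C observed/expected);
#'   `"max_p"` keeps links with score `<= value` (score read as p value).
#' @param value Fraction in (0, 1\] or p-value cutoff.
#' @return The retained subset.
#' @export
threshold_links <- function(links, mode = c("top_fraction", "max_p"), value) {
  mode <- match.arg(mode)
  if (mode == "top_fraction") {
    if (value <= 0 || value > 1) abort("top_fraction must lie in (0, 1]")
    m <- ceiling(value * nrow(links))
    ord <- order(-links$score, links$distance, links$start_a)
    links[sort(ord[seq_len(m)]), ]
  } else {
    links[!is.na(links$score) & links$score <= value, ]
  }
}

#' Randomly shift links along the chromosome
#'
#' Both anchors of a link are translated by the same signed offset, drawn
#' uniformly from the union of \[-max_shift, -min_shift\] and
#' \[min_shift, max_shift\], so span length and distance class are
#' preserved. Offsets are clipped so the span stays within the chromosome.
#' Used as a local control: links sitting at a rate-valley centre should
#' show a (slightly) higher rate after shifting.
#'
#' @param links A link table.
#' @param assembly A [genome_assembly()].
#' @param min_shift,max_shift Shift magnitude bounds in bp
#'   (defaults 1-5 kb); `min_shift` must be > 0.
#' @return The shifted link table.
#' @export
shift_links <- function(links, assembly, min_shift = 1000, max_shift = 5000) {
  if (min_shift <= 0 || max_shift < min_shift) {
    abort("need 0 < min_shift <= max_shift")
  }
  n <- nrow(links)
  offset <- sample(c(-1, 1), n, replace = TRUE) *
    runif(n, min_shift, max_shift)
  len <- assembly_lengths(assembly)[links$chrom]
  offset <- pmax(offset, -links$span_start)
  offset <- pmin(offset, len - links$span_end)
  offset <- round(offset)
  links$start_a <- links$start_a + offset
  links$end_a <- links$end_a + offset
  links$start_b <- links$start_b + offset
  links$end_b <- links$end_b + offset
  relink(links)
}

#' Split links into constitutive and tissue-specific
#'
#' A link is constitutive when a link with both anchors within
#' `anchor_tolerance` of its own exists in at least `min_tissues` of the
#' supplied tissue link sets (itself included). Returns the union of all
#' sets, labelled.
#'
#' @param linksets_by_tissue Named list of link tables (>= 2).
#' @param min_tissues Minimum number of tissues sharing the link.
#' @param anchor_tolerance Anchor midpoint tolerance in bp (default 1000).
#' @return List with `constitutive` and `specific` link tables (each with a
#'   `tissue` and `n_tissues` column) partitioning the union.
#' @export
classify_constitutive <- function(linksets_by_tissue, min_tissues = 2,
                                  anchor_tolerance = 1000) {
  if (length(linksets_by_tissue) < 2) abort("need >= 2 tissue link sets")
  if (is.null(names(linksets_by_tissue))) {
    names(linksets_by_tissue) <- paste0("tissue", seq_along(linksets_by_tissue))
  }
  all_links <- purrr::imap_dfr(linksets_by_tissue,
                               function(l, nm) dplyr::mutate(l, tissue = nm))
  mids <- purrr::map(linksets_by_tissue, function(l) {
    tibble(chrom = l$chrom,
           mid_a = (l$start_a + l$end_a) / 2,
           mid_b = (l$start_b + l$end_b) / 2)
  })
  qa <- (all_links$start_a + all_links$end_a) / 2
  qb <- (all_links$start_b + all_links$end_b) / 2
  n_tissues <- integer(nrow(all_links))
  for (j in seq_len(nrow(all_links))) {
    n_tissues[j] <- sum(vapply(mids, function(m) {
      any(m$chrom == all_links$chrom[j] &
            abs(m$mid_a - qa[j]) <= anchor_tolerance &
            abs(m$mid_b - qb[j]) <= anchor_tolerance)
    }, logical(1)))
  }
  all_links$n_tissues <- n_tissues
  list(constitutive = all_links[n_tissues >= min_tissues, ],
       specific = all_links[n_tissues < min_tissues, ])
}

#' Predict activity links from peak signal / expression correlation
#'
#' For every peak-gene pair within `max_distance` (peak midpoint to TSS),
#' computes the Pearson correlation of peak signal and gene expression
#' across cell types and emits a link when `r >= r_threshold`. Pairs where
#' either profile has zero variance are skipped (a single warning reports
#' the count).
#'
#' @param peaks Interval tibble of peaks with a `peak_id` column.
#' @param peak_signal Numeric matrix, peaks x cell types, rownames =
#'   `peak_id`.
#' @param expression Numeric matrix, genes x cell types (same column
#'   order), rownames = gene ids.
#' @param tss Tibble with `chrom`, `pos`, `gene`.
#' @param max_distance Distance gate in bp (default 1 Mb).
#' @param r_threshold Minimum correlation (default 0.7).
#' @return A link table (`link_type = "DNase_TSS"`, score = r,
#'   target_id = gene).
#' @export
predict_activity_links <- function(peaks, peak_signal, expression, tss,
                                   max_distance = 1e6, r_threshold = 0.7) {
  if (ncol(peak_signal) < 3 || ncol(expression) != ncol(peak_signal)) {
    abort("need >= 3 cell types, identical across both matrices")
  }
  peak_mid <- (peaks$start + peaks$end) / 2
  n_skipped <- 0L
  rows <- purrr::map_dfr(seq_len(nrow(tss)), function(g) {
    gene <- tss$gene[g]
    if (!gene %in% rownames(expression)) return(NULL)
    e <- expression[gene, ]
    near <- which(peaks$chrom == tss$chrom[g] &
                    abs(peak_mid - tss$pos[g]) <= max_distance)
    if (length(near) == 0) return(NULL)
    sig <- peak_signal[peaks$peak_id[near], , drop = FALSE]
    var0 <- apply(sig, 1, sd) == 0 | sd(e) == 0
    n_skipped <<- n_skipped + sum(var0)
    near <- near[!var0]
    if (length(near) == 0) return(NULL)
    r <- as.numeric(cor(t(peak_signal[peaks$peak_id[near], , drop = FALSE]), e))
    hit <- which(r >= r_threshold)
    if (length(hit) == 0) return(NULL)
    tibble(chrom = tss$chrom[g],
           start_a = peaks$start[near[hit]], end_a = peaks$end[near[hit]],
           start_b = tss$pos[g], end_b = tss$pos[g] + 1,
           score = r[hit], target_id = gene)
  })
  if (n_skipped > 0) warn(paste0("skipped ", n_skipped, " zero-variance pair(s)"))
  if (nrow(rows) == 0) {
    rows <- tibble(chrom = character(), start_a = numeric(), end_a = numeric(),
                   start_b = numeric(), end_b = numeric(), score = numeric(),
                   target_id = character())
  }
  as_links(rows, link_type = "DNase_TSS")
}
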