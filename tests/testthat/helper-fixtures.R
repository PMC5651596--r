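# Shared fixtures and independent oracles. Everything is built in code; the
# oracles deliberately use a different algorithm than the implementation
# they check.

tiny_map <- function() {
  genetic_map(tibble::tibble(chrom = "chr1", pos = c(1000, 2000, 4000),
                             cum_cm = c(0, 0.01, 0.05)))
}

tiny_assembly <- function() genome_assembly(c("chr1", "chr2"), c(1e6, 1e6))

# small fast scenario for unit tests (cached per session)
.scn_cache <- new.env(parent = emptyenv())
small_scenario <- function(name = "planted_valley", seed = 42) {
  key <- paste(name, seed)
  if (is.null(.scn_cache[[key]])) {
    .scn_cache[[key]] <- make_scenario(
      name, seed = seed,
      chrom_length = 5e6, n_domains = 12, domain_length = c(1e5, 3e5),
      n_links = 120, snp_spacing = 1000, n_ctcf = 100, n_extra_tss = 300)
  }
  .scn_cache[[key]]
}

# marker-by-marker rate oracle: sums each inter-marker segment's cM overlap
# explicitly instead of interpolating endpoint cumulative values
oracle_interval_rate <- function(map, chrom, start, end) {
  d <- map[map$chrom == chrom, ]
  total_cm <- 0
  for (i in seq_len(nrow(d) - 1)) {
    seg_lo <- d$pos[i]; seg_hi <- d$pos[i + 1]
    ov <- min(end, seg_hi) - max(start, seg_lo)
    if (ov > 0) {
      seg_rate_per_bp <- (d$cum_cm[i + 1] - d$cum_cm[i]) / (seg_hi - seg_lo)
      total_cm <- total_cm + ov * seg_rate_per_bp
    }
  }
  total_cm / ((end - start) / 1e6)
}

# brute-force k-nearest neighbours by full scan
oracle_knn <- function(points, query, k) {
  d <- sqrt(colSums((t(points) - query)^2))
  order(d)[seq_len(min(k, nrow(points)))]
}

# full 2^n enumeration of the signed-rank null: two-sided p for observed W
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  Ws <- signs %*% r
  p_le <- mean(Ws <= W + 1e-12)
  p_ge <- mean(Ws >= W - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}

# constant-value feature track over an assembly
constant_track <- function(assembly, value, name = "const", bin_size = 1000) {
  bins <- purrr::map_dfr(seq_len(nrow(assembly)), function(i) {
    n_bin <- ceiling(assembly$length[i] / bin_size)
    tibble::tibble(chrom = assembly$chrom[i],
                   start = (seq_len(n_bin) - 1) * bin_size, value = value)
  })
  feature_track(bins, bin_size = bin_size, feature_name = name)
}

point_links <- function(chrom, pos_a, pos_b, ...) {
  as_links(tibble::tibble(chrom = chrom, start_a = pos_a, end_a = pos_a + 1,
                          start_b = pos_b, end_b = pos_b + 1, ...))
}
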