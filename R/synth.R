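#' Synthetic scenario configuration
#'
#' Parameters of the synthetic genome generator. The generator emulates the
#' statistical structure the valley analysis assumes: a piecewise-constant
#' recombination landscape (baseline plus short hotspots), planted
#' domain-shaped rate valleys, link sets whose spans preferentially fall
#' inside those domains, spatially autocorrelated feature tracks for
#' control matching, and a CpG methylation track negatively coupled to the
#' local recombination rate.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Chromosome length (bp).
#' @param snp_spacing Genetic-map marker spacing (bp).
#' @param baseline_rate Background rate (cM/Mb).
#' @param hotspot_per_mb Hotspot count per Mb.
#' @param hotspot_width Hotspot width (bp).
#' @param hotspot_multiplier Rate multiplier inside hotspots.
#' @param n_domains Planted domains (across the genome).
#' @param domain_length c(min, max) domain length (bp).
#' @param valley_multiplier Rate multiplier inside domains, in (0, 1].
#' @param n_links Number of links.
#' @param link_distance c(min, max) anchor distance (bp).
#' @param inside_fraction Fraction of links with span inside a domain
#'   (under `link_placement = "domain_biased"`).
#' @param link_placement `"domain_biased"` (the valley mechanism: links
#'   cluster inside domains) or `"uniform"` (anchors anywhere; the null
#'   condition, where domain membership carries no rate effect and links
#'   must not share local landscape through forced co-location).
#' @param meth_coupling Target correlation between methylation and local
#'   rate, in \[-1, 1\].
#' @param meth_noise_sd Iid CpG-level noise sd (on the \[0, 1\] scale).
#' @param meth_field_bp Correlation length of the smooth methylation noise
#'   field (bp); keeps window-level correlations near `meth_coupling`.
#' @param cpg_spacing CpG spacing (bp).
#' @param track_smoothness Feature-track moving-average window (1-kb bins);
#'   the default 300 mirrors the several-hundred-kb autocorrelation of GC
#'   and CpG landscapes (isochore scale).
#' @param n_ctcf CTCF motifs per chromosome.
#' @param ctcf_inside_domains Plant motifs inside domains too (for
#'   interruption-filter tests); default FALSE, mirroring analysis of
#'   CTCF-uninterrupted link sets.
#' @param n_extra_tss Extra random TSS points per chromosome (enriches the
#'   null pair universe).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_chromosomes = 2, chrom_length = 2e7,
                            snp_spacing = 500, baseline_rate = 1.0,
                            hotspot_per_mb = 5, hotspot_width = 2000,
                            hotspot_multiplier = 10,
                            n_domains = 40, domain_length = c(1e5, 4e5),
                            valley_multiplier = 0.5,
                            n_links = 400, link_distance = c(1e4, 6e5),
                            inside_fraction = 0.9,
                            link_placement = c("domain_biased", "uniform"),
                            meth_coupling = -0.5, meth_noise_sd = 0.02,
                            meth_field_bp = 1e5, cpg_spacing = 200,
                            track_smoothness = 300, n_ctcf = 500,
                            ctcf_inside_domains = FALSE, n_extra_tss = 1000) {
  cfg <- as.list(environment())
  cfg$link_placement <- match.arg(link_placement)
  stopifnot(cfg$valley_multiplier > 0, cfg$valley_multiplier <= 1,
            cfg$inside_fraction >= 0, cfg$inside_fraction <= 1,
            cfg$meth_coupling >= -1, cfg$meth_coupling <= 1,
            cfg$baseline_rate > 0, cfg$chrom_length > 0)
  structure(cfg, class = "scenario_config")
}

scenario_assembly <- function(config) {
  genome_assembly(paste0("chr", seq_len(config$n_chromosomes)),
                  rep(config$chrom_length, config$n_chromosomes))
}

#' Synthetic genetic map with planted valleys and hotspots
#'
#' Markers sit every `snp_spacing` bp; the rate of each inter-marker
#' segment is `baseline_rate`, multiplied by `valley_multiplier` inside a
#' planted domain and by `hotspot_multiplier` inside a hotspot (effects
#' multiply where they overlap). Cumulative cM comes from integrating the
#' piecewise-constant rate. Domains are non-overlapping.
#'
#' @param config A [scenario_config()].
#' @return List: `map` ([genetic_map()]), `domains`, `hotspots` (interval
#'   tibbles).
#' @export
synth_genetic_map <- function(config) {
  assembly <- scenario_assembly(config)
  domains <- place_domains(config, assembly)
  hotspots <- purrr::map_dfr(assembly$chrom, function(cn) {
    n_h <- round(config$hotspot_per_mb * config$chrom_length / 1e6)
    if (n_h == 0) return(NULL)
    s <- floor(runif(n_h, 0, config$chrom_length - config$hotspot_width))
    tibble(chrom = cn, start = sort(s), end = sort(s) + config$hotspot_width)
  })
  if (nrow(hotspots) == 0) {
    hotspots <- tibble(chrom = character(), start = numeric(), end = numeric())
  }
  map <- purrr::map_dfr(assembly$chrom, function(cn) {
    pos <- seq(0, config$chrom_length, by = config$snp_spacing)
    mid <- head(pos, -1) + config$snp_spacing / 2
    rate <- rep(config$baseline_rate, length(mid))
    in_dom <- point_in_intervals(cn, mid, domains)
    rate[in_dom] <- rate[in_dom] * config$valley_multiplier
    in_hot <- point_in_intervals(cn, mid, hotspots)
    rate[in_hot] <- rate[in_hot] * config$hotspot_multiplier
    tibble(chrom = cn, pos = pos,
           cum_cm = c(0, cumsum(rate * config$snp_spacing / 1e6)))
  })
  list(map = genetic_map(map), domains = domains, hotspots = hotspots)
}

place_domains <- function(config, assembly) {
  n_per <- diff(c(0, round(seq_len(nrow(assembly)) * config$n_domains /
                             nrow(assembly))))
  purrr::map_dfr(seq_len(nrow(assembly)), function(i) {
    n <- n_per[i]
    if (n == 0) return(NULL)
    lens <- round(runif(n, config$domain_length[1], config$domain_length[2]))
    if (sum(lens) > assembly$length[i]) {
      abort("domains infeasible: total domain length exceeds the chromosome")
    }
    # place by spreading the free space between domains at random
    free <- assembly$length[i] - sum(lens)
    gaps <- diff(c(0, sort(floor(runif(n, 0, free + 1))), free))[seq_len(n)]
    starts <- cumsum(gaps) + cumsum(c(0, head(lens, -1)))
    tibble(chrom = assembly$chrom[i], start = starts, end = starts + lens)
  })
}

point_in_intervals <- function(chrom, pos, intervals) {
  iv <- intervals[intervals$chrom == chrom, ]
  if (nrow(iv) == 0) return(rep(FALSE, length(pos)))
  iv <- dplyr::arrange(iv, .data$start)
  k <- findInterval(pos, iv$start)
  k > 0 & pos < iv$end[pmax(k, 1)]
}

#' Synthetic link set with domain-biased placement
#'
#' A fraction `inside_fraction` of links is placed with the full span
#' inside a random planted domain (anchor distance drawn from the
#' configured range, clipped to the domain length); the rest are placed
#' uniformly with spans intersecting no domain. Anchors are 1-bp points;
#' each link gets its own target id and a random p-value-like score.
#'
#' @param config A [scenario_config()].
#' @param domains Domain intervals from [synth_genetic_map()].
#' @param link_type Link type tag (default `"eQTL"`).
#' @return A link table.
#' @export
synth_links <- function(config, domains, link_type = "eQTL") {
  assembly <- scenario_assembly(config)
  d_lo <- config$link_distance[1]; d_hi <- config$link_distance[2]
  if ((config$link_placement %||% "domain_biased") == "uniform") {
    n <- config$n_links
    ci <- sample.int(nrow(assembly), n, replace = TRUE)
    d <- floor(runif(n, d_lo, d_hi + 1))
    a <- floor(runif(n) * (assembly$length[ci] - d - 1))
    out <- tibble(chrom = assembly$chrom[ci], start_a = a, end_a = a + 1,
                  start_b = a + d, end_b = a + d + 1)
    out$score <- 10^(-runif(n, 4, 12))
    out$target_id <- paste0("T", seq_len(n))
    return(as_links(out, link_type = link_type))
  }
  n_in <- round(config$inside_fraction * config$n_links)
  n_out <- config$n_links - n_in
  rows <- list()
  if (n_in > 0) {
    if (nrow(domains) == 0) abort("inside links requested but no domains exist")
    feasible <- domains[domains$end - domains$start > d_lo + 1, ]
    if (nrow(feasible) == 0) abort("link distance range infeasible for all domains")
    di <- sample.int(nrow(feasible), n_in, replace = TRUE)
    dlen <- feasible$end[di] - feasible$start[di]
    d <- floor(runif(n_in, d_lo, pmin(d_hi, dlen - 1) + 1))
    a <- feasible$start[di] + floor(runif(n_in) * (dlen - d - 1))
    rows$inside <- tibble(chrom = feasible$chrom[di], start_a = a, end_a = a + 1,
                          start_b = a + d, end_b = a + d + 1)
  }
  if (n_out > 0) {
    got <- 0; acc <- list(); tries <- 0
    while (got < n_out && tries < 200) {
      tries <- tries + 1
      m <- (n_out - got) * 2 + 10
      ci <- sample.int(nrow(assembly), m, replace = TRUE)
      d <- floor(runif(m, d_lo, d_hi + 1))
      a <- floor(runif(m) * (assembly$length[ci] - d - 1))
      cand <- tibble(chrom = assembly$chrom[ci], start = a, end = a + d + 1)
      ok <- !intervals_overlap_any(cand, domains)
      keep <- which(ok)[seq_len(min(sum(ok), n_out - got))]
      if (length(keep) > 0) {
        acc[[length(acc) + 1]] <- tibble(chrom = cand$chrom[keep],
                                         start_a = cand$start[keep],
                                         end_a = cand$start[keep] + 1,
                                         start_b = cand$start[keep] + d[keep],
                                         end_b = cand$start[keep] + d[keep] + 1)
        got <- got + length(keep)
      }
    }
    if (got < n_out) abort("could not place links outside domains")
    rows$outside <- dplyr::bind_rows(acc)
  }
  out <- dplyr::bind_rows(rows)
  out$score <- 10^(-runif(nrow(out), 4, 12))
  out$target_id <- paste0("T", seq_len(nrow(out)))
  as_links(out, link_type = link_type)
}

# smoothed standardized random field over n points (moving average of white
# noise; circular to avoid edge attenuation)
smooth_field <- function(n, window) {
  if (window >= n) return(rep(0, n))
  x <- rnorm(n + window)
  f <- as.numeric(stats::filter(x, rep(1 / window, window), sides = 2,
                                circular = TRUE))[seq_len(n)]
  as.numeric(scale(f))
}

#' Synthetic matching-feature tracks
#'
#' Spatially autocorrelated tracks in realistic ranges: GC fraction, CpG
#' density, SNP density, and PRDM9 motif density. Each is a moving-average
#' smoothed Gaussian field (window `track_smoothness` bins) scaled to its
#' range; an infinite smoothness window degenerates to a constant track.
#'
#' @param config A [scenario_config()].
#' @param bin_size Track bin size (bp, default 1000).
#' @return Named list of [feature_track()]s.
#' @export
synth_tracks <- function(config, bin_size = 1000) {
  assembly <- scenario_assembly(config)
  track_defs <- list(gc = c(0.45, 0.06), cpg_density = c(0.02, 0.008),
                     snp_density = c(0.005, 0.002), prdm9_density = c(0.001, 4e-4))
  purrr::imap(track_defs, function(cs, nm) {
    bins <- purrr::map_dfr(seq_len(nrow(assembly)), function(i) {
      n_bin <- ceiling(assembly$length[i] / bin_size)
      v <- cs[1] + cs[2] * smooth_field(n_bin, config$track_smoothness)
      tibble(chrom = assembly$chrom[i], start = (seq_len(n_bin) - 1) * bin_size,
             value = pmax(v, 0))
    })
    feature_track(bins, bin_size = bin_size, feature_name = nm)
  })
}

#' Synthetic CpG methylation coupled to the recombination landscape
#'
#' CpGs sit every `cpg_spacing` bp. The level at each CpG is an affine map
#' of the standardized local recombination rate — smoothed over
#' `meth_field_bp`, the methylation-domain scale — with target correlation
#' `meth_coupling`, mixed with an independent random field of the same
#' correlation length carrying the residual variance, plus iid noise, and
#' clipped to \[0, 1\]. Matching the correlation lengths of signal and
#' noise keeps the realized correlation near the target when both tracks
#' are aggregated into windows, because aggregation then shrinks both
#' components equally.
#'
#' @param config A [scenario_config()].
#' @param map A [genetic_map()].
#' @return A [methylation_track()].
#' @export
synth_methylation <- function(config, map) {
  assembly <- scenario_assembly(config)
  rho <- config$meth_coupling
  w <- max(2, round(config$meth_field_bp / config$cpg_spacing))
  out <- purrr::map_dfr(assembly$chrom, function(cn) {
    d <- map_chrom(map, cn)
    seg_rate <- diff(d$cum_cm) / (diff(d$pos) / 1e6)
    pos <- seq(config$cpg_spacing, assembly$length[assembly$chrom == cn] - 1,
               by = config$cpg_spacing)
    rate_at <- seg_rate[pmin(findInterval(pos, d$pos), length(seg_rate))]
    rate_smooth <- as.numeric(stats::filter(rate_at, rep(1 / w, w), sides = 2,
                                            circular = TRUE))
    z <- if (sd(rate_smooth) > 0) as.numeric(scale(rate_smooth)) else
      rep(0, length(pos))
    eta <- smooth_field(length(pos), w)
    lv <- 0.5 + 0.15 * (rho * z + sqrt(max(0, 1 - rho^2)) * eta) +
      rnorm(length(pos), 0, config$meth_noise_sd)
    tibble(chrom = cn, pos = pos, level = pmin(1, pmax(0, lv)))
  })
  methylation_track(out)
}

synth_ctcf <- function(config, domains) {
  assembly <- scenario_assembly(config)
  purrr::map_dfr(assembly$chrom, function(cn) {
    got <- tibble(chrom = character(), start = numeric(), end = numeric())
    tries <- 0
    while (nrow(got) < config$n_ctcf && tries < 100) {
      tries <- tries + 1
      m <- (config$n_ctcf - nrow(got)) * 2 + 10
      s <- floor(runif(m, 0, assembly$length[assembly$chrom == cn] - 19))
      cand <- tibble(chrom = cn, start = s, end = s + 19)
      if (!config$ctcf_inside_domains) {
        cand <- cand[!intervals_overlap_any(cand, domains), ]
      }
      got <- head(dplyr::bind_rows(got, cand), config$n_ctcf)
    }
    dplyr::arrange(got, .data$start)
  })
}

derive_seed <- function(seed, stage) {
  stages <- c(scenario = 1L, controls = 2L, test = 3L, methyl = 4L,
              predict = 5L, report = 6L, shift = 7L)
  as.integer((as.numeric(seed) * 10007 + stages[[stage]]) %% (.Machine$integer.max - 1))
}

#' Generate a complete synthetic scenario
#'
#' Presets:
#' * `planted_valley` — the reference study condition: 2 chromosomes of
#'   20 Mb, markers every 500 bp, baseline 1 cM/Mb, 40 domains of
#'   100-400 kb with rate multiplier 0.5, 400 links (90 percent inside
#'   domains) at 10-600 kb distances.
#' * `null` — `valley_multiplier = 1` (domains carry no rate effect) with
#'   uniform link placement; forcing links into shared domains would leave
#'   the marginal rates unchanged but cluster the paired differences, which
#'   is a dependence artefact rather than a rate-null condition.
#' * `methylation_coupled` — `planted_valley` with strong methylation
#'   coupling (`meth_coupling = -0.8`, low noise).
#'
#' The whole bundle is a deterministic function of `(name, seed)`.
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @param ... `scenario_config()` overrides applied on top of the preset.
#' @return List: `name`, `seed`, `config`, `assembly`, `map`, `domains`,
#'   `hotspots`, `links`, `tracks`, `ctcf_motifs`, `methylation`, `snps`,
#'   `tss`, and `truth` (the ground-truth manifest).
#' @export
make_scenario <- function(name = c("planted_valley", "null", "methylation_coupled"),
                          seed = 1, ...) {
  if (!is.character(name) || !name[1] %in% c("planted_valley", "null",
                                             "methylation_coupled")) {
    abort(paste0("unknown preset '", name[1],
                 "'; available: planted_valley, null, methylation_coupled"))
  }
  name <- name[1]
  preset <- switch(name,
    planted_valley = list(),
    null = list(valley_multiplier = 1, link_placement = "uniform"),
    methylation_coupled = list(meth_coupling = -0.8, meth_noise_sd = 0.01))
  config <- do.call(scenario_config, utils::modifyList(preset, list(...)))
  set.seed(derive_seed(seed, "scenario"))
  assembly <- scenario_assembly(config)
  gm <- synth_genetic_map(config)
  links <- synth_links(config, gm$domains)
  tracks <- synth_tracks(config)
  ctcf <- synth_ctcf(config, gm$domains)
  meth <- synth_methylation(config, gm$map)
  snps <- tibble(chrom = gm$map$chrom, pos = gm$map$pos)
  tss <- dplyr::bind_rows(
    tibble(chrom = links$chrom, pos = links$start_b),
    purrr::map_dfr(assembly$chrom, function(cn) {
      tibble(chrom = cn,
             pos = sort(floor(runif(config$n_extra_tss, 0,
                                    assembly$length[assembly$chrom == cn]))))
    })) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$chrom, .data$pos)
  list(name = name, seed = seed, config = config, assembly = assembly,
       map = gm$map, domains = gm$domains, hotspots = gm$hotspots,
       links = links, tracks = tracks, ctcf_motifs = ctcf,
       methylation = meth, snps = snps, tss = tss,
       truth = list(config = unclass(config), domains = gm$domains,
                    hotspots = gm$hotspots))
}

#' Write a scenario to disk in standard formats
#'
#' Map as chrom/pos/rate/cum-cM text (1-based positions), links as BEDPE,
#' tracks and methylation as bedGraph, domains/hotspots/motifs/SNPs/TSS as
#' BED, plus an `auto.yaml` pipeline config pointing at the files.
#'
#' @param scenario A [make_scenario()] result.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  map <- scenario$map
  rate_col <- unlist(tapply(seq_len(nrow(map)), map$chrom, function(i) {
    r <- diff(map$cum_cm[i]) / (diff(map$pos[i]) / 1e6)
    c(r, 0)
  }))
  readr::write_tsv(tibble(chrom = map$chrom, pos = map$pos + 1,
                          rate = rate_col, cum_cm = map$cum_cm),
                   p("genetic_map.txt"), col_names = FALSE, progress = FALSE)
  write_links(scenario$links, p("links.bedpe"))
  for (nm in names(scenario$tracks)) {
    tr <- scenario$tracks[[nm]]
    b <- track_bin_size(tr)
    len <- assembly_lengths(scenario$assembly)[tr$chrom]
    readr::write_tsv(tibble(chrom = tr$chrom, start = tr$start,
                            end = pmin(tr$start + b, len), value = tr$value),
                     p(paste0("track_", nm, ".bedgraph")),
                     col_names = FALSE, progress = FALSE)
  }
  write_methylation(scenario$methylation, p("methylation.bedgraph"))
  write_intervals(scenario$domains, p("domains.bed"))
  if (nrow(scenario$hotspots) > 0) write_intervals(scenario$hotspots, p("hotspots.bed"))
  write_intervals(scenario$ctcf_motifs, p("ctcf_motifs.bed"))
  write_intervals(tibble(chrom = scenario$snps$chrom, start = scenario$snps$pos,
                         end = scenario$snps$pos + 1), p("snps.bed"))
  write_intervals(tibble(chrom = scenario$tss$chrom, start = scenario$tss$pos,
                         end = scenario$tss$pos + 1), p("tss.bed"))
  readr::write_tsv(scenario$assembly, p("assembly.tsv"), progress = FALSE)
  cfg <- list(
    scenario = scenario$name, seed = scenario$seed,
    paths = list(dir = ".", genetic_map = "genetic_map.txt",
                 links = "links.bedpe", domains = "domains.bed",
                 hotspots = "hotspots.bed", ctcf_motifs = "ctcf_motifs.bed",
                 methylation = "methylation.bedgraph",
                 assembly = "assembly.tsv", snps = "snps.bed", tss = "tss.bed",
                 tracks = as.list(setNames(
                   paste0("track_", names(scenario$tracks), ".bedgraph"),
                   names(scenario$tracks)))),
    control_strategy = "length", tolerance = 0.01, max_iter = 10000,
    k = 1000, n_perm = 10000, alpha = 1e-4, window = 5e5, n_quantiles = 10,
    cv_folds = 5, num_trees = 500)
  yaml::write_yaml(cfg, p("auto.yaml"))
  invisible(dir)
}
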