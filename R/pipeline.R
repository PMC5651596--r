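VALID_CONFIG_KEYS <- c(
  "scenario", "preset", "seed", "paths", "control_strategy", "tolerance",
  "max_iter", "k", "n_perm", "alpha", "window", "n_quantiles", "cv_folds",
  "num_trees", "n_bins", "n_predict_intervals", "out", "link_format",
  "link_type", "grid", "length_step", "subsample", "n_perm_labels")

load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("no such config file: ", config))
    cfg <- yaml::read_yaml(config)
    cfg$.dir <- dirname(config)
  } else {
    cfg <- config
    cfg$.dir <- cfg$.dir %||% "."
  }
  bad <- setdiff(names(cfg), c(VALID_CONFIG_KEYS, ".dir"))
  if (length(bad) > 0) {
    abort(paste0("invalid config key(s): ", paste(bad, collapse = ", "),
                 "\nvalid keys: ", paste(VALID_CONFIG_KEYS, collapse = ", ")))
  }
  cfg
}

cfg_path <- function(cfg, key) {
  p <- cfg$paths[[key]]
  if (is.null(p)) return(NULL)
  fp <- file.path(cfg$.dir, cfg$paths$dir %||% ".", p)
  if (!file.exists(fp)) abort(paste0("missing input path for '", key, "': ", fp))
  fp
}

load_inputs <- function(cfg, need = c("assembly", "map", "links")) {
  inp <- list()
  if ("assembly" %in% need) {
    a <- readr::read_tsv(cfg_path(cfg, "assembly"), show_col_types = FALSE,
                         progress = FALSE)
    inp$assembly <- genome_assembly(a$chrom, a$length)
  }
  if ("map" %in% need) {
    inp$map <- read_genetic_map(cfg_path(cfg, "genetic_map"),
                                dialect = "pos_rate_cm")
  }
  if ("links" %in% need) {
    inp$links <- read_links(cfg_path(cfg, "links"),
                            format = cfg$link_format %||% "bedpe",
                            link_type = cfg$link_type %||% "eQTL",
                            assembly = inp$assembly)
  }
  if ("tracks" %in% need && !is.null(cfg$paths$tracks)) {
    inp$tracks <- purrr::imap(cfg$paths$tracks, function(rel, nm) {
      read_track(file.path(cfg$.dir, cfg$paths$dir %||% ".", rel),
                 inp$assembly, feature_name = nm)
    })
  }
  if ("methylation" %in% need && !is.null(cfg$paths$methylation)) {
    inp$methylation <- read_methylation(cfg_path(cfg, "methylation"),
                                        inp$assembly)
  }
  if ("domains" %in% need && !is.null(cfg$paths$domains)) {
    inp$domains <- read_intervals(cfg_path(cfg, "domains"), inp$assembly)
  }
  if ("hotspots" %in% need && !is.null(cfg$paths$hotspots)) {
    inp$hotspots <- read_intervals(cfg_path(cfg, "hotspots"), inp$assembly)
  }
  if ("ctcf" %in% need && !is.null(cfg$paths$ctcf_motifs)) {
    inp$ctcf <- read_intervals(cfg_path(cfg, "ctcf_motifs"), inp$assembly)
  }
  if ("points" %in% need) {
    snp <- read_intervals(cfg_path(cfg, "snps"))
    tss <- read_intervals(cfg_path(cfg, "tss"))
    inp$points_a <- tibble(chrom = snp$chrom, pos = snp$start)
    inp$points_b <- tibble(chrom = tss$chrom, pos = tss$start)
  }
  inp
}

log_run <- function(stage, seed, cfg) {
  fp <- substr(rlang::hash(cfg[setdiff(names(cfg), ".dir")]), 1, 8)
  inform(paste0("[", stage, "] seed=", seed, " config=", fp))
}

#' Run a pipeline stage
#'
#' Config-driven driver tying the stages together; each subcommand reads
#' its declared inputs, runs the corresponding package functions with a
#' stage-derived seed, writes TSV/JSON outputs next to the config (or under
#' `out`), and logs the seed and a config fingerprint. A single global
#' `seed` fans out to deterministic per-stage child seeds.
#'
#' Subcommands: `simulate` (preset -> scenario files), `rates`
#' (distance-binned mean rates), `controls` (matched controls TSV), `test`
#' (the valley test), `group-compare` (valley depth between the
#' CTCF-uninterrupted and interrupted subsets), `methyl` (window
#' correlation + methylation-quantile profile), `predict` (random-forest
#' rate predictor on random intervals), `report` (merge stage JSONs).
#'
#' @param subcommand One of the above.
#' @param config Path to a YAML config, or a config list.
#' @param overrides Named list overriding config keys.
#' @return The stage's result object, invisibly (also written to disk).
#' @export
rv_run <- function(subcommand = c("simulate", "rates", "controls", "test",
                                  "group-compare", "methyl", "predict", "report"),
                   config = NULL, overrides = list()) {
  subcommand <- match.arg(subcommand)
  cfg <- load_config(config %||% list())
  cfg[names(overrides)] <- overrides
  seed <- as.integer(cfg$seed %||% 1)
  out_dir <- file.path(cfg$.dir, cfg$out %||% ".")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  o <- function(...) file.path(out_dir, ...)

  if (subcommand == "simulate") {
    log_run("simulate", seed, cfg)
    scn <- make_scenario(cfg$preset %||% "planted_valley", seed = seed)
    write_scenario(scn, out_dir)
    return(invisible(scn))
  }

  if (subcommand == "rates") {
    set.seed(derive_seed(seed, "test"))
    log_run("rates", seed, cfg)
    inp <- load_inputs(cfg, c("assembly", "map", "links"))
    ctrl <- sample_length_matched(inp$links, inp$assembly)
    res <- mean_rate_by_distance(inp$links, inp$map,
                                 n_bins = cfg$n_bins %||% 100, controls = ctrl)
    readr::write_tsv(res, o("rates_by_distance.tsv"), progress = FALSE)
    return(invisible(res))
  }

  if (subcommand == "controls") {
    set.seed(derive_seed(seed, "controls"))
    log_run("controls", seed, cfg)
    inp <- load_inputs(cfg, c("assembly", "map", "links", "tracks", "domains", "ctcf"))
    strategy <- cfg$control_strategy %||% "length"
    ctrl <- switch(strategy,
      length = sample_length_matched(inp$links, inp$assembly),
      rejection = sample_feature_matched_rejection(
        inp$links, inp$assembly, inp$tracks,
        tolerance = cfg$tolerance %||% 0.01,
        max_iter = cfg$max_iter %||% 10000),
      kdtree = {
        idx <- build_candidate_index(inp$assembly, inp$tracks,
                                     grid = cfg$grid %||% 1000,
                                     length_step = cfg$length_step %||% 1000,
                                     subsample = cfg$subsample %||% 1)
        sample_kdtree_matched(idx, inp$links, k = cfg$k %||% 1000,
                              ctcf_motifs = inp$ctcf)
      },
      domain = sample_within_domain(inp$links, inp$domains),
      abort(paste0("unknown control_strategy: ", strategy)))
    readr::write_tsv(ctrl, o("controls.tsv"), progress = FALSE)
    return(invisible(ctrl))
  }

  if (subcommand == "test") {
    set.seed(derive_seed(seed, "test"))
    log_run("test", seed, cfg)
    inp <- load_inputs(cfg, c("assembly", "map", "links", "tracks", "domains",
                              "ctcf", "points"))
    res <- valley_test(inp$links, inp$map, inp$assembly,
                       control_strategy = cfg$control_strategy %||% "length",
                       tracks = inp$tracks, domains = inp$domains,
                       points_a = inp$points_a, points_b = inp$points_b,
                       n_perm = cfg$n_perm %||% 10000,
                       alpha = cfg$alpha %||% 1e-4)
    write_results(res, o("valley_test.json"))
    write_results(res, o("valley_test.tsv"))
    return(invisible(res))
  }

  if (subcommand == "group-compare") {
    set.seed(derive_seed(seed, "test"))
    log_run("group-compare", seed, cfg)
    inp <- load_inputs(cfg, c("assembly", "map", "links", "ctcf"))
    parts <- filter_ctcf_uninterrupted(inp$links, inp$ctcf)
    if (nrow(parts$interrupted) == 0 || nrow(parts$uninterrupted) == 0) {
      abort("group-compare needs both CTCF-interrupted and uninterrupted links")
    }
    res <- group_compare(parts$uninterrupted, parts$interrupted, inp$map,
                         inp$assembly,
                         n_perm_labels = cfg$n_perm_labels %||% 10000)
    jsonlite::write_json(res, o("group_compare.json"), auto_unbox = TRUE,
                         digits = NA)
    return(invisible(res))
  }

  if (subcommand == "methyl") {
    set.seed(derive_seed(seed, "methyl"))
    log_run("methyl", seed, cfg)
    inp <- load_inputs(cfg, c("assembly", "map", "links", "methylation"))
    wc <- window_correlation(inp$methylation, inp$map, inp$assembly,
                             window = cfg$window %||% 5e5)
    qp <- quantile_rate_profile(inp$links, inp$methylation, inp$map,
                                n_quantiles = cfg$n_quantiles %||% 10)
    jsonlite::write_json(wc, o("window_correlation.json"), auto_unbox = TRUE,
                         digits = NA)
    readr::write_tsv(qp, o("quantile_profile.tsv"), progress = FALSE)
    return(invisible(list(window_correlation = wc, quantile_profile = qp)))
  }

  if (subcommand == "predict") {
    set.seed(derive_seed(seed, "predict"))
    log_run("predict", seed, cfg)
    inp <- load_inputs(cfg, c("assembly", "map", "links", "methylation", "hotspots"))
    n_iv <- cfg$n_predict_intervals %||% 2000
    ci <- sample.int(nrow(inp$assembly), n_iv, replace = TRUE)
    len <- floor(runif(n_iv, 1e4, 1e6))
    s <- floor(runif(n_iv) * (inp$assembly$length[ci] - len))
    ivs <- tibble(chrom = inp$assembly$chrom[ci], start = s, end = s + len)
    feats <- interval_feature_table(ivs, list(eQTL = inp$links),
                                    methylation = inp$methylation,
                                    hotspots = inp$hotspots)
    rates <- interval_rate(inp$map, ivs)$rate
    fit <- train_rate_predictor(feats, rates,
                                cv_folds = cfg$cv_folds %||% 5,
                                num_trees = cfg$num_trees %||% 500)
    jsonlite::write_json(as.list(glance(fit)), o("predictor.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(fit))
  }

  # report: merge whatever stage outputs exist
  log_run("report", seed, cfg)
  pieces <- list()
  for (f in c("valley_test.json", "group_compare.json",
              "window_correlation.json", "predictor.json")) {
    fp <- o(f)
    if (file.exists(fp)) {
      pieces[[sub("\\.json$", "", f)]] <- jsonlite::read_json(fp,
                                                              simplifyVector = TRUE)
    }
  }
  if (length(pieces) == 0) abort("report: no stage outputs found")
  jsonlite::write_json(pieces, o("summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(pieces)
}
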