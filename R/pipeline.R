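#' Packaged reference tables
#'
#' The package ships the item codebook of a 32-item mental-health
#' knowledge/stigma instrument (20 MHKQ knowledge items, 12 PDD stigma
#' items) and its published per-item endorsement counts from a large
#' school survey (N = 12,537). The counts anchor the synthetic generator's
#' default endorsement-rate targets (spanning roughly 14%-92%) and let the
#' descriptive routines be checked against printed values.
#'
#' @param which `"codebook"`, `"counts"` (per-item endorsement counts) or
#'   `"sample"` (demographic counts of the reference sample).
#' @return A data frame.
#' @export
reference_table <- function(which = c("codebook", "counts", "sample")) {
  which <- match.arg(which)
  file <- switch(which,
    codebook = "mhkq_pdd_codebook.csv",
    counts = "mhkq_pdd_reference_counts.csv",
    sample = "sample_reference_counts.csv")
  path <- system.file("extdata", file, package = "isingnet", mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (which == "codebook") out <- validate_codebook(out)
  out
}

#' Generate a synthetic study bundle
#'
#' Builds a ground-truth two-community network (20 knowledge + 12 stigma
#' items, planted bridges), calibrates its thresholds so item endorsement
#' rates emulate the packaged reference counts (~14%-92%), Gibbs-samples
#' `n` respondents, and optionally writes a ready-to-analyze bundle:
#' `responses.csv` (raw labels through the codebook, plus a null `group`
#' column), `codebook.csv`, and the ground-truth network
#' (`true_network.json`).
#'
#' @param dir output directory (created if needed); `NULL` skips writing.
#' @param n number of respondents.
#' @param seed integer seed governing network, calibration, sampling and
#'   group labels through named substreams.
#' @param n_bridges,intra_density,weight_range,tau_range passed to
#'   [make_true_network()].
#' @param calibrate logical; calibrate thresholds to the reference
#'   endorsement rates (default TRUE).
#' @param burn_in Gibbs sweeps per respondent.
#' @return List with `network` (ground truth), `responses`
#'   ([response_matrix()]), `codebook`, `targets`, and file `paths` (if
#'   written).
#' @export
generate_demo <- function(dir = NULL, n = 2000, seed = 1,
                          n_bridges = 3, intra_density = 0.15,
                          weight_range = c(0.3, 1.2),
                          tau_range = c(-4.5, -1.0),
                          calibrate = TRUE, burn_in = 1000) {
  cb <- reference_table("codebook")
  counts <- reference_table("counts")
  targets <- counts$n_endorsed / (counts$n_endorsed + counts$n_not_endorsed)

  net <- make_true_network(
    p_knowledge = sum(cb$community == "knowledge"),
    p_stigma = sum(cb$community == "stigma"),
    intra_density = intra_density, n_bridges = n_bridges,
    weight_range = weight_range, tau_range = tau_range,
    seed = substream_seed(seed, "net"))
  if (calibrate)
    net <- calibrate_thresholds(net, targets,
                                seed = substream_seed(seed, "calibrate"))
  X <- gibbs_sample(net, sim_config(n = n, burn_in = burn_in,
                                    seed = substream_seed(seed, "sample")))
  group <- with_seed(substream_seed(seed, "group"),
                     sample(c("female", "male"), n, replace = TRUE,
                            prob = c(0.61, 0.39)))
  X <- response_matrix(X$values, item_ids = cb$item_id, group = group,
                       check_variance = FALSE)

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      responses = file.path(dir, "responses.csv"),
      codebook = file.path(dir, "codebook.csv"),
      network = file.path(dir, "true_network.json"))
    write_responses(X, paths$responses, codebook = cb)
    write_codebook(cb, paths$codebook)
    write_network(net, paths$network, "json")
  }
  list(network = net, responses = X, codebook = cb, targets = targets,
       seed = seed, paths = paths)
}

default_pipeline_config <- function() {
  list(
    responses = NULL, codebook = NULL, out_dir = "isingnet-output",
    group_col = NULL, seed = 1,
    estimation = list(gamma = 0.25, rule = "AND", n_lambda = 100,
                      lambda_min_ratio = 0.01),
    stability = list(grid = seq(0.1, 0.75, 0.05), reps = 500,
                     metrics = c("strength", "expected_influence")),
    nira = list(magnitude = 2, n_persons = NULL, burn_in = 1000),
    nct = list(n_perm = 1000),
    stages = list(descriptives = TRUE, estimate = TRUE, centrality = TRUE,
                  stability = TRUE, nira = TRUE, nct = TRUE)
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Run the full analysis pipeline
#'
#' Orchestrates load -> descriptives -> eLasso estimation -> centrality ->
#' stability -> threshold-perturbation simulation -> group comparison from
#' one configuration, writing plain CSV/JSON artifacts and a run manifest.
#' Rerunning with the same configuration and seed reproduces every numeric
#' output exactly (stages draw from named substreams of the global seed,
#' so toggling one stage does not shift another's randomness).
#'
#' @param config a configuration list, or the path of a YAML/JSON file
#'   holding one. Recognized fields (all optional except `responses` and
#'   `codebook`): `out_dir`, `group_col`, `seed`, and the stage blocks
#'   `estimation` (gamma, rule, n_lambda, lambda_min_ratio), `stability`
#'   (grid, reps, metrics), `nira` (magnitude, n_persons, burn_in), `nct`
#'   (n_perm), `stages` (logical toggles per stage).
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      yaml::read_yaml(config) else jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  cfg <- merge_config(default_pipeline_config(), config)
  if (is.null(cfg$responses) || is.null(cfg$codebook))
    stop("config must name 'responses' and 'codebook' files")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(
    package = "isingnet",
    package_version = as.character(utils::packageVersion("isingnet")),
    r_version = R.version.string,
    seed = cfg$seed,
    config = cfg,
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list()
  )
  results <- list()
  out <- function(f) file.path(cfg$out_dir, f)

  stage <- function(name, enabled, fun) {
    if (!enabled) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    t0 <- proc.time()[3]
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed", error = conditionMessage(e))
      write_manifest(manifest, out("manifest.json"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok", seconds = round(proc.time()[3] - t0, 2))
    results[[name]] <<- res
    res
  }

  cb <- read_codebook(cfg$codebook)
  X <- load_responses(cfg$responses, cb, group_col = cfg$group_col)
  ecfg <- estimation_config(gamma = cfg$estimation$gamma,
                            n_lambda = cfg$estimation$n_lambda,
                            lambda_min_ratio = cfg$estimation$lambda_min_ratio,
                            rule = cfg$estimation$rule)

  stage("descriptives", cfg$stages$descriptives, function() {
    d <- descriptive_table(X)
    utils::write.csv(d, out("descriptives.csv"), row.names = FALSE)
    d
  })

  net <- stage("estimate", cfg$stages$estimate, function() {
    net <- estimate_network(X, ecfg, communities = cb$community)
    write_network(net, out("network.json"), "json")
    write_network(net, out("network_edges.csv"), "csv")
    net
  })

  stage("centrality", cfg$stages$centrality, function() {
    ct <- centrality_table(net)
    utils::write.csv(ct, out("centrality.csv"), row.names = FALSE)
    ct
  })

  stage("stability", cfg$stages$stability, function() {
    sb <- case_drop_bootstrap(X, grid = cfg$stability$grid,
                              reps = cfg$stability$reps,
                              metrics = cfg$stability$metrics,
                              cfg = ecfg, communities = cb$community,
                              seed = substream_seed(cfg$seed, "stability"))
    utils::write.csv(sb$correlations, out("stability_correlations.csv"),
                     row.names = FALSE)
    cs <- cs_coefficient(sb)
    jsonlite::write_json(list(cs_coefficient = as.list(cs),
                              n_skipped = sb$n_skipped),
                         out("stability_summary.json"), auto_unbox = TRUE,
                         digits = NA)
    list(result = sb, cs = cs)
  })

  stage("nira", cfg$stages$nira, function() {
    np <- cfg$nira$n_persons
    if (is.null(np)) np <- nrow(X$values)
    nr <- run_nira(net, magnitude = cfg$nira$magnitude, n_persons = np,
                   cfg = sim_config(burn_in = cfg$nira$burn_in),
                   seed = substream_seed(cfg$seed, "nira"))
    utils::write.csv(as.data.frame(nr), out("nira.csv"), row.names = FALSE)
    nr
  })

  stage("nct", cfg$stages$nct && !is.null(X$group), function() {
    gr <- unique(X$group)
    if (length(gr) != 2) stop("nct stage needs exactly two groups, found ",
                              length(gr))
    res <- nct_test(X$values[X$group == gr[1], , drop = FALSE],
                    X$values[X$group == gr[2], , drop = FALSE],
                    n_perm = cfg$nct$n_perm, cfg = ecfg,
                    seed = substream_seed(cfg$seed, "nct"))
    jsonlite::write_json(list(
      groups = gr,
      global_strength = as.list(res$global_strength),
      global_strength_diff = res$global_strength_diff,
      global_strength_p = res$global_strength_p,
      max_edge_diff = res$max_edge_diff,
      structure_p = res$structure_p,
      n_perm = res$n_perm
    ), out("nct.json"), auto_unbox = TRUE, digits = NA)
    res
  })

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  write_manifest(manifest, out("manifest.json"))
  invisible(c(results, list(manifest = manifest)))
}

write_manifest <- function(manifest, path) {
  cfg_json <- jsonlite::toJSON(manifest$config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest$config_md5 <- unname(tools::md5sum(tmp))
  unlink(tmp)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
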