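# CSV dialect: UTF-8, comma, header, "." decimal, 10 significant digits
.fmt_num <- function(x) {
  if (is.numeric(x)) formatC(x, digits = 10, format = "g") else as.character(x)
}

.write_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, .fmt_num), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Default pipeline configuration
#'
#' A fully populated configuration list running the `vhh_contrast`
#' generator preset; every key can be overridden in a YAML config file or
#' by supplying a modified list to [run_pipeline()].
#'
#' @param output_dir output directory.
#' @param seed base seed for the generator.
#' @return named configuration list.
#' @export
default_config <- function(output_dir = "cdrflex_out", seed = 1) {
  list(
    seed = seed,
    output_dir = output_dir,
    generator = list(preset = "vhh_contrast"),
    inputs = NULL,           # alternative to generator: list(reference=,
                             # trajectories = c(...), numbering = "identity")
    regions = list(scheme = "imgt", overrides = NULL),
    q_params = list(beta = 5, lambda = 1.8, contact_cutoff = 4.5,
                    min_seq_separation = 3),
    burn_in_fraction = 6 / 11,
    convergence = list(std_threshold = 1.0, overlap_threshold = 0.5,
                       outlier_k = 3, outlier_min_abs = 0.5,
                       split_after_burn_in = TRUE,
                       exclude_outliers = FALSE),
    exclude_runs = character(0),
    kde = list(grid_points = 512, bandwidth = NULL, rmsd_region = "CDR1"),
    write_plots = FALSE
  )
}

#' Validate a pipeline configuration
#'
#' Checks bounds and referenced paths, collecting every violation rather
#' than stopping at the first.
#'
#' @param config a configuration list, or the path of a YAML file holding
#'   one (keys merge over [default_config()]).
#' @return the validated (merged) configuration, invisibly; an error listing
#'   every violation otherwise.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: '", config, "'")
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  merged <- utils::modifyList(default_config(), config,
                              keep.null = TRUE)
  # a config that supplies inputs (and no generator of its own) means
  # "analyze these files", not the default generator preset
  if (!is.null(merged$inputs) && !("generator" %in% names(config)))
    merged$generator <- NULL
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  qp <- merged$q_params
  chk(is.numeric(qp$beta) && qp$beta > 0, "q_params.beta must be > 0")
  chk(is.numeric(qp$lambda) && qp$lambda >= 1, "q_params.lambda must be >= 1")
  chk(is.numeric(qp$contact_cutoff) && qp$contact_cutoff > 0,
      "q_params.contact_cutoff must be > 0")
  chk(qp$min_seq_separation >= 0, "q_params.min_seq_separation must be >= 0")
  chk(is.numeric(merged$burn_in_fraction) &&
        merged$burn_in_fraction >= 0 && merged$burn_in_fraction < 1,
      "burn_in_fraction must lie in [0, 1)")
  cv <- merged$convergence
  chk(cv$std_threshold > 0, "convergence.std_threshold must be > 0")
  chk(cv$overlap_threshold >= 0 && cv$overlap_threshold <= 1,
      "convergence.overlap_threshold must lie in [0, 1]")
  chk(cv$outlier_k > 0, "convergence.outlier_k must be > 0")
  chk(merged$kde$grid_points >= 16, "kde.grid_points must be >= 16")
  if (!is.null(merged$kde$bandwidth))
    chk(merged$kde$bandwidth > 0, "kde.bandwidth must be > 0")
  if (is.null(merged$generator) && is.null(merged$inputs))
    chk(FALSE, "one of generator or inputs must be given")
  if (!is.null(merged$inputs)) {
    chk(file.exists(merged$inputs$reference %||% ""),
        "inputs.reference file not found")
    for (tp in merged$inputs$trajectories)
      chk(file.exists(tp), paste0("inputs.trajectories: '", tp,
                                  "' not found"))
    nb <- merged$inputs$numbering %||% "identity"
    if (!identical(nb, "identity"))
      chk(file.exists(nb), "inputs.numbering file not found")
  }
  if (!is.null(merged$regions$overrides)) {
    sch <- try(region_scheme(lapply(merged$regions$overrides, unlist)),
               silent = TRUE)
    if (inherits(sch, "try-error"))
      chk(FALSE, paste0("regions.overrides invalid: ",
                        attr(sch, "condition")$message))
  }
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  invisible(merged)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_scheme <- function(config) {
  if (!is.null(config$regions$overrides))
    region_scheme(lapply(config$regions$overrides, unlist))
  else imgt_scheme()
}

# assemble the per-system inputs (reference, annotation, run ensembles)
.pipeline_systems <- function(config) {
  if (!is.null(config$generator)) {
    pr <- preset(config$generator$preset %||% "vhh_contrast",
                 base_seed = config$seed)
    list(broad = list(reference = pr$scaffold, annotation = pr$annotation,
                      ensembles = generate_ensemble(pr$broad)),
         narrow = list(reference = pr$scaffold, annotation = pr$annotation,
                       ensembles = generate_ensemble(pr$narrow)))
  } else {
    inp <- config$inputs
    ref <- read_pdb(inp$reference, chain = inp$chain %||% NULL)
    nb <- inp$numbering %||% "identity"
    num <- if (identical(nb, "identity")) identity_numbering(ref)
           else read_numbering_tsv(nb)
    ann <- assign_regions(num, .config_scheme(config))
    ens <- lapply(seq_along(inp$trajectories), function(k)
      read_multimodel_pdb(inp$trajectories[k], chain = inp$chain %||% NULL,
                          run_id = paste0("RUN-", k)))
    stats::setNames(list(list(reference = ref, annotation = ann,
                              ensembles = ens)),
                    inp$name %||% "system")
  }
}

.analyze_system <- function(sys, config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ref <- sys$reference; ann <- sys$annotation; ens <- sys$ensembles
  run_ids <- vapply(ens, function(e) e$run_id, character(1))
  names(ens) <- run_ids
  qp <- do.call(q_params, config$q_params)
  contacts <- find_native_contacts(ref, qp)
  write_contacts_csv(contacts, file.path(outdir, "contacts.csv"))

  cdr_regions <- c("CDR1", "CDR2", "CDR3")
  glob <- lapply(ens, global_rmsd_series, reference = ref)
  per_cdr <- lapply(cdr_regions, function(rg)
    lapply(ens, cdr_rmsd_series, reference = ref, annotation = ann,
           region = rg))
  names(per_cdr) <- cdr_regions
  qs <- lapply(ens, q_series, contacts = contacts)

  .write_csv(rmsd_series_table(c(glob, unlist(per_cdr, recursive = FALSE))),
             file.path(outdir, "rmsd_series.csv"))
  .write_csv(do.call(rbind, lapply(run_ids, function(id)
    data.frame(run_id = id, frame = seq_along(qs[[id]]), q = qs[[id]]))),
    file.path(outdir, "q_series.csv"))

  # convergence on the global CA RMSD
  cv <- config$convergence
  reports <- lapply(run_ids, function(id)
    convergence_report(glob[[id]], run_id = id,
                       burn_in_fraction = config$burn_in_fraction,
                       std_threshold = cv$std_threshold,
                       overlap_threshold = cv$overlap_threshold,
                       split_after_burn_in = cv$split_after_burn_in))
  names(reports) <- run_ids
  outliers <- if (length(ens) >= 3)
    flag_outlier_runs(lapply(glob, function(s)
      discard_burn_in(s$values, config$burn_in_fraction)),
      k = cv$outlier_k, min_abs = cv$outlier_min_abs %||% 0.5)
  else character(0)
  for (id in outliers) reports[[id]]$is_outlier <- TRUE
  .write_json(lapply(reports, unclass),
              file.path(outdir, "convergence.json"))
  .write_csv(do.call(rbind, lapply(reports, function(r)
    as.data.frame(unclass(r), stringsAsFactors = FALSE))),
    file.path(outdir, "convergence.csv"))

  excl <- unique(c(config$exclude_runs,
                   if (isTRUE(cv$exclude_outliers)) outliers))
  excl <- intersect(excl, run_ids)

  tail_of <- function(series_by_run)
    lapply(series_by_run, function(s)
      discard_burn_in(if (inherits(s, "cdr_rmsd_series")) s$values else s,
                      config$burn_in_fraction))
  rg <- config$kde$rmsd_region
  pooled_rmsd <- pool_runs(tail_of(per_cdr[[rg]]), exclude = excl)
  pooled_q <- pool_runs(tail_of(qs), exclude = excl)

  prof_rmsd <- kde_profile(pooled_rmsd, grid_points = config$kde$grid_points,
                           bandwidth = config$kde$bandwidth)
  prof_q <- kde_profile(pooled_q, grid_points = config$kde$grid_points,
                        bandwidth = config$kde$bandwidth)
  .write_csv(data.frame(grid = prof_rmsd$grid, density = prof_rmsd$density),
             file.path(outdir, paste0("density_", tolower(rg), "_rmsd.csv")))
  .write_csv(data.frame(grid = prof_q$grid, density = prof_q$density),
             file.path(outdir, "density_q.csv"))
  side <- function(p) list(sample_mean = p$sample_mean,
                           sample_std = p$sample_std,
                           raw_bandwidth = p$raw_bandwidth,
                           n_samples = p$n_samples,
                           n_runs_pooled = p$n_runs_pooled,
                           degenerate = p$degenerate)
  .write_json(list(rmsd = side(prof_rmsd), q = side(prof_q)),
              file.path(outdir, "density_summary.json"))

  corr <- q_rmsd_correlation(pooled_q$value, pooled_rmsd$value,
                             run_id = pooled_q$run_id)
  .write_json(list(pearson_r = corr$pearson_r,
                   spearman_rho = corr$spearman_rho,
                   n_points = corr$n_points,
                   constant_input = corr$constant_input,
                   per_run = corr$per_run),
              file.path(outdir, "correlation.json"))

  region_means <- lapply(cdr_regions, function(r2) {
    v <- unlist(tail_of(per_cdr[[r2]])[setdiff(run_ids, excl)])
    list(mean = mean(v), std = stats::sd(v))
  })
  names(region_means) <- cdr_regions

  if (isTRUE(config$write_plots)) {
    grDevices::png(file.path(outdir, "density_profiles.png"),
                   width = 900, height = 400)
    graphics::par(mfrow = c(1, 2))
    plot(prof_rmsd, main = paste(rg, "RMSD"),
         xlab = "RMSD (Angstrom)")
    plot(prof_q, main = "Q", xlab = "Q")
    grDevices::dev.off()
    grDevices::png(file.path(outdir, "q_vs_rmsd.png"), width = 500,
                   height = 500)
    graphics::plot(pooled_rmsd$value, pooled_q$value, pch = 20, cex = 0.4,
                   xlab = paste(rg, "RMSD (Angstrom)"), ylab = "Q")
    grDevices::dev.off()
  }

  summary <- list(
    n_runs = length(ens),
    n_frames_per_run = vapply(ens, n_frames, integer(1)),
    excluded_runs = excl,
    outlier_runs = outliers,
    n_runs_pooled = attr(pooled_q, "n_runs_pooled"),
    n_native_contacts = contacts$N,
    burn_in_fraction = config$burn_in_fraction,
    convergence_all_passed = all(vapply(reports, function(r)
      r$passed_std && r$passed_overlap, logical(1))),
    region_rmsd = region_means,
    q = list(mean = mean(pooled_q$value), std = stats::sd(pooled_q$value)),
    rmsd_profile = side(prof_rmsd),
    q_profile = side(prof_q),
    correlation = list(pearson_r = corr$pearson_r,
                       spearman_rho = corr$spearman_rho))
  .write_json(summary, file.path(outdir, "summary.json"))
  summary
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) → annotate → analyze → report. Per system the
#' pipeline writes: contacts.csv, rmsd_series.csv (global + per-CDR),
#' q_series.csv, convergence.json/.csv, pooled density CSVs with a JSON
#' sidecar, correlation.json and summary.json; a top-level manifest echoes
#' the configuration, package version and seed. A stage failure aborts with
#' a stage-named error and leaves an INCOMPLETE marker file in the output
#' directory. Identical configuration and inputs give byte-identical
#' outputs.
#'
#' @param config configuration list or YAML path; see [default_config()]
#'   and [validate_config()].
#' @return (invisibly) named list of per-system summaries plus `compare`
#'   (breadth comparison) when two systems were analyzed.
#' @export
run_pipeline <- function(config = default_config()) {
  config <- validate_config(config)
  outdir <- config$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(outdir, "INCOMPLETE")
  file.create(marker)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  systems <- stage("simulate/load", .pipeline_systems(config))
  results <- list()
  for (nm in names(systems))
    results[[nm]] <- stage(paste0("analyze:", nm),
                           .analyze_system(systems[[nm]], config,
                                           file.path(outdir, nm)))
  if (length(results) == 2L) {
    prof <- lapply(names(systems), function(nm) {
      ss <- results[[nm]]
      list(rmsd_std = ss$rmsd_profile$sample_std,
           rmsd_mean = ss$rmsd_profile$sample_mean,
           q_std = ss$q_profile$sample_std,
           q_mean = ss$q_profile$sample_mean)
    })
    names(prof) <- names(systems)
    a <- prof[[1L]]; b <- prof[[2L]]
    results$compare <- list(
      systems = names(systems),
      rmsd_broader = names(systems)[which.max(c(a$rmsd_std, b$rmsd_std))],
      q_broader = names(systems)[which.max(c(a$q_std, b$q_std))],
      q_mean_shift = a$q_mean - b$q_mean,
      rmsd_std = c(a$rmsd_std, b$rmsd_std),
      q_std = c(a$q_std, b$q_std))
    .write_json(results$compare, file.path(outdir, "compare.json"))
  }
  manifest <- list(package = "cdrflex",
                   version = as.character(utils::packageVersion("cdrflex")),
                   seed = config$seed,
                   config = config)
  .write_json(manifest, file.path(outdir, "manifest.json"))
  file.remove(marker)
  invisible(results)
}
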