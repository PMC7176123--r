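#' Split-chain Gelman-Rubin potential scale reduction
#'
#' Each chain is halved, giving `2C` sequences of equal length; the statistic
#' compares between- and within-sequence variance. Values near 1 indicate
#' convergence; the conventional flag threshold is 1.1. A constant set of
#' chains is degenerate (no variance to compare): the statistic is returned
#' as 1 with attribute `degenerate = TRUE`.
#'
#' @param draws iterations x chains matrix of draws of one scalar parameter
#'   (at least 2 chains).
#' @return split R-hat (numeric scalar, possibly with `degenerate` attr).
#' @export
gelman_rubin <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2L) stop("split R-hat needs at least 2 chains")
  L <- nrow(draws) %/% 2L
  if (L < 2L) stop("chains too short to split")
  halves <- do.call(cbind, lapply(seq_len(ncol(draws)), function(c)
    cbind(draws[seq_len(L), c], draws[L + seq_len(L), c])))
  W <- mean(apply(halves, 2, stats::var))
  if (W == 0) return(structure(1, degenerate = TRUE))
  B <- L * stats::var(colMeans(halves))
  sqrt(((L - 1) / L * W + B / L) / W)
}

#' Effective sample size
#'
#' Geyer initial-positive-sequence estimator: per chain, autocovariances are
#' summed over consecutive lag pairs until a pair goes negative; chain ESS
#' values add across chains.
#'
#' @param draws iterations x chains matrix (a vector is one chain).
#' @return estimated effective sample size.
#' @export
effective_size <- function(draws) {
  draws <- as.matrix(draws)
  ess1 <- function(x) {
    L <- length(x)
    if (stats::var(x) == 0) return(L)
    rho <- stats::acf(x, lag.max = min(L - 1L, 1000L), plot = FALSE,
                      demean = TRUE)$acf[, 1, 1]
    s <- 0
    t <- 1L
    while (t + 1L < length(rho)) {
      pair <- rho[t + 1L] + rho[t + 2L]
      if (pair < 0) break
      s <- s + pair
      t <- t + 2L
    }
    L / (1 + 2 * s)
  }
  sum(apply(draws, 2, ess1))
}

#' Join district summaries onto a GeoJSON map layer
#'
#' Annotates each feature of a polygon FeatureCollection with the numeric
#' columns of a district summary table (spatial odds, prevalence,
#' exceedance, ...), matching feature id to district code 1:1. Unmatched
#' codes on either side are an error naming them.
#'
#' @param district_summaries data frame with a `code` column and numeric
#'   attribute columns.
#' @param geojson_in input GeoJSON path.
#' @param geojson_out output path.
#' @param id_property feature property holding the district code.
#' @return `geojson_out`, invisibly.
#' @export
export_map_layer <- function(district_summaries, geojson_in, geojson_out,
                             id_property = "id") {
  stopifnot(is.data.frame(district_summaries),
            "code" %in% names(district_summaries))
  gj <- jsonlite::fromJSON(geojson_in, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("GeoJSON input is not a FeatureCollection")
  codes <- vapply(gj$features, function(f)
    as.character(f$properties[[id_property]]), character(1))
  want <- as.character(district_summaries$code)
  missing_in_map <- setdiff(want, codes)
  missing_in_table <- setdiff(codes, want)
  if (length(missing_in_map) || length(missing_in_table))
    stop("district codes do not join 1:1; unmatched: ",
         paste(c(missing_in_map, missing_in_table), collapse = ", "))
  attrs <- district_summaries[vapply(district_summaries, is.numeric,
                                     logical(1))]
  for (i in seq_along(gj$features)) {
    row <- match(codes[i], want)
    for (v in names(attrs))
      gj$features[[i]]$properties[[v]] <- attrs[[v]][row]
  }
  jsonlite::write_json(gj, geojson_out, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(geojson_out)
}

.pipeline_defaults <- function() {
  list(seed = 1, rows = 4, cols = 5,
       diseases = c("hbp", "ihd", "stroke", "dyslip"),
       chains = 2, iterations = 2000, burnin = 1000, thin = 2,
       model = "both",
       formula = "~ sex + age_group + diabetes + bmi_class",
       size_meanlog = log(130), size_sdlog = 0.45, size_range = c(40, 400))
}

#' Run the full mapping pipeline
#'
#' simulate -> derive outcomes -> survey estimation -> fit model A (individual
#' and household covariates) -> fit model B (A plus the district deprivation
#' quintile) -> summarise. All stage outputs are written under `run_dir` and
#' a JSON manifest (config echo, seeds, package version, per-parameter split
#' R-hat, converged flags, stage status) is written at its root; the manifest
#' plus seed reproduce the run exactly.
#'
#' The default demo configuration is a 4 x 5 lattice geography with roughly
#' 2,600 participants and 2 chains of 2,000 sweeps — small enough to run in
#' about a minute while exercising every stage.
#'
#' @param config named list overriding the defaults (`seed`, `rows`, `cols`,
#'   `diseases`, `chains`, `iterations`, `burnin`, `thin`, `model` ("A", "B"
#'   or "both"), `formula`, size-law fields), or the path to a YAML file of
#'   the same keys.
#' @param run_dir output directory (created if needed).
#' @return the manifest, invisibly (class `run_manifest`).
#' @export
run_pipeline <- function(config = list(), run_dir = tempfile("mcarmap_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.pipeline_defaults(), config)
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = cfg, package_version =
                     as.character(utils::packageVersion("mcarmap")),
                   stages = list())
  stage <- function(name, fun) {
    res <- tryCatch(list(ok = TRUE, value = fun()),
                    error = function(e) list(ok = FALSE,
                                             error = conditionMessage(e)))
    manifest$stages[[name]] <<- if (res$ok) list(status = "ok")
      else list(status = "failed", error = res$error)
    if (!res$ok) {
      # a failed run still leaves a manifest recording stage and cause
      jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, na = "null",
                           force = TRUE)
      stop("pipeline stage '", name, "' failed: ", res$error)
    }
    res$value
  }

  graph <- lattice_graph(cfg$rows, cfg$cols)
  fml <- stats::as.formula(cfg$formula)

  sim <- stage("simulate", function() {
    gc_ <- generator_config(graph = graph, diseases = cfg$diseases,
                            formula = fml,
                            size_meanlog = cfg$size_meanlog,
                            size_sdlog = cfg$size_sdlog,
                            size_range = cfg$size_range)
    pop <- generate_population(gc_, seed = cfg$seed)
    utils::write.csv(pop$records, file.path(run_dir, "participants.csv"),
                     row.names = FALSE)
    write_winbugs_adj(graph, file.path(run_dir, "adjacency.txt"))
    pop
  })

  sampi_tab <- stage("sampi", function() {
    tab <- make_district_sampi(graph, spatial = TRUE, seed = cfg$seed + 1)
    utils::write.csv(tab, file.path(run_dir, "district_sampi.csv"),
                     row.names = FALSE)
    tab
  })

  derived <- stage("derive", function() {
    out <- derive_outcomes(sim$records)
    utils::write.csv(out, file.path(run_dir, "outcomes.csv"),
                     row.names = FALSE)
    out
  })

  stage("estimate", function() {
    y <- derived$hbp
    tab <- stratified_prevalence(y, sim$records$weight, sim$records$sex)
    utils::write.csv(tab, file.path(run_dir, "prevalence_by_sex.csv"),
                     row.names = FALSE)
    dp <- district_prevalence(y, sim$records$weight, sim$records$district,
                              graph)
    utils::write.csv(dp, file.path(run_dir, "district_prevalence.csv"),
                     row.names = FALSE)
    dp
  })

  y <- as.matrix(derived[, intersect(cfg$diseases, names(derived)),
                         drop = FALSE])
  covs <- sim$records
  covs$sampi_quintile <- sampi_tab$quintile[covs$district]

  fits <- list()
  if (cfg$model %in% c("A", "both")) {
    fits$A <- stage("fit_A", function() {
      spec <- mcar_spec(y, covs$district, graph, covs, fml)
      run_mcmc(spec, chains = cfg$chains, iterations = cfg$iterations,
               burnin = cfg$burnin, thin = cfg$thin, seed = cfg$seed)
    })
  }
  if (cfg$model %in% c("B", "both")) {
    fits$B <- stage("fit_B", function() {
      fml_b <- stats::update(fml, ~ . + sampi_quintile)
      spec <- mcar_spec(y, covs$district, graph, covs, fml_b)
      run_mcmc(spec, chains = cfg$chains, iterations = cfg$iterations,
               burnin = cfg$burnin, thin = cfg$thin, seed = cfg$seed)
    })
  }

  stage("summarize", function() {
    for (m in names(fits)) {
      utils::write.csv(posterior_or_table(fits[[m]]),
                       file.path(run_dir, paste0("or_table_", m, ".csv")),
                       row.names = FALSE)
      utils::write.csv(spatial_odds(fits[[m]]),
                       file.path(run_dir, paste0("spatial_odds_", m, ".csv")),
                       row.names = FALSE)
    }
    invisible(NULL)
  })

  manifest$models <- lapply(fits, function(f)
    list(rhat = as.list(f$rhat), ess = as.list(f$ess),
         converged = isTRUE(f$converged), config = f$config))
  manifest$run_dir <- run_dir
  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest),
                       file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest:", x$run_dir, "\n")
  for (s in names(x$stages))
    cat(sprintf("  %-10s %s\n", s, x$stages[[s]]$status))
  for (m in names(x$models))
    cat(sprintf("  model %s: converged = %s\n", m, x$models[[m]]$converged))
  invisible(x)
}
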