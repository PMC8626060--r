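# Experiment orchestration: simulate or ingest cubes, calibrate, segment,
# partition, compute indices, run regime statistics, and rank acquisition
# conditions (organ x region x angle) by coefficient of determination.

#' Experiment configuration
#'
#' @param mode `"simulate"` (generate cubes with [simulate_leaf_cube()]) or
#'   `"directory"` (read every `*.hdr` under `input_dir`; cubes must carry
#'   organ/angle/regime/plant metadata in their headers).
#' @param input_dir directory of ENVI cubes for `mode = "directory"`.
#' @param organs organs to evaluate.
#' @param angles shooting angles to evaluate (degrees).
#' @param regions leaf regions to evaluate (1..5 = apex..base).
#' @param n_per_regime simulated plants per regime (>= 3).
#' @param predictor regression predictor, `"total_n"` or `"regime_index"`.
#' @param seed master seed; all per-cube seeds derive from it.
#' @param out_dir optional output directory for CSV reports.
#' @param params generator parameters ([sim_params()]).
#' @param calibrate if `TRUE`, run [calibrate_visible_ratio()] for the leaf
#'   organs before simulating.
#' @param cube_size simulated cube size; overrides `params$cube_size`.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(mode = c("simulate", "directory"),
                              input_dir = NULL,
                              organs = c("spike", "flag_leaf", "second_leaf"),
                              angles = c(105, 125),
                              regions = 1:5,
                              n_per_regime = 10L,
                              predictor = c("total_n", "regime_index"),
                              seed = 1L,
                              out_dir = NULL,
                              params = sim_params(),
                              calibrate = TRUE,
                              cube_size = c(64L, 64L)) {
  mode <- match.arg(mode)
  predictor <- match.arg(predictor)
  if (!length(organs) || !length(angles)) {
    stop("need at least one organ and one angle", call. = FALSE)
  }
  organs <- match.arg(organs, c("spike", "flag_leaf", "second_leaf"),
                      several.ok = TRUE)
  if (mode == "simulate" && n_per_regime < 3L) {
    stop("n_per_regime must be >= 3 for the regime statistics", call. = FALSE)
  }
  if (mode == "directory" && (is.null(input_dir) || !dir.exists(input_dir))) {
    stop("mode 'directory' needs an existing input_dir", call. = FALSE)
  }
  if (!length(organs) || !length(angles)) {
    stop("need at least one organ and one angle", call. = FALSE)
  }
  if (!is.null(cube_size)) params$cube_size <- as.integer(cube_size)
  structure(
    list(mode = mode, input_dir = input_dir, organs = organs,
         angles = as.numeric(angles), regions = as.integer(regions),
         n_per_regime = as.integer(n_per_regime), predictor = predictor,
         seed = as.integer(seed), out_dir = out_dir, params = params,
         calibrate = isTRUE(calibrate)),
    class = "experiment_config"
  )
}

#' Read an experiment configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [experiment_config()]; a `params`
#' block is forwarded to [sim_params()].
#'
#' @param path YAML file path.
#' @return An [experiment_config()] object.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  pargs <- y$params
  y$params <- NULL
  params <- if (is.null(pargs)) sim_params() else {
    for (nm in c("cab_n1", "cab_n6", "deficit_scale", "pnir_n1", "pnir_n6",
                 "glint_sigma", "visible_ratio_target")) {
      if (!is.null(pargs[[nm]])) pargs[[nm]] <- unlist(pargs[[nm]])
    }
    do.call(sim_params, pargs)
  }
  do.call(experiment_config, c(y, list(params = params)))
}

# deterministic per-cube seed stream derived from the master seed
# (double arithmetic: products exceed .Machine$integer.max)
.cube_seed <- function(master, i) {
  as.integer((as.numeric(master) * 1009 + as.numeric(i) * 7919) %% 2147483647)
}

# simulate (or load) all cubes of the experiment; returns list of
# list(cube, labels=NULL for loaded cubes)
.gather_cubes <- function(config) {
  if (config$mode == "directory") {
    hdrs <- sort(list.files(config$input_dir, pattern = "\\.hdr$", full.names = TRUE))
    if (!length(hdrs)) stop("no .hdr files under ", config$input_dir, call. = FALSE)
    return(lapply(hdrs, function(h) list(cube = read_envi_cube(h), labels = NULL)))
  }
  params <- config$params
  if (config$calibrate) {
    for (org in intersect(config$organs, names(params$visible_ratio_target))) {
      params <- calibrate_visible_ratio(params, org)
    }
  }
  design <- params$design
  out <- list(); i <- 0L
  for (regime in design$regime) {
    for (plant in seq_len(config$n_per_regime)) {
      plant_id <- sprintf("%s_p%02d", regime, plant)
      plant_seed <- .cube_seed(config$seed, match(regime, design$regime) * 1000L + plant)
      for (org in config$organs) {
        for (ang in config$angles) {
          i <- i + 1L
          out[[i]] <- simulate_leaf_cube(
            params, regime, org, angle = ang,
            seed = .cube_seed(config$seed, i), plant_id = plant_id,
            plant_seed = plant_seed)
        }
      }
    }
  }
  attr(out, "params") <- params
  out
}

#' Run the full acquisition-condition experiment
#'
#' Simulates (or ingests) one cube per plant, organ and angle, re-detects the
#' organ mask and five-region partition from the image (the generator's
#' ground truth is not reused), computes the four vegetation indices from
#' region-mean spectra, and then for every (organ, region, angle, index)
#' cell regresses the index on the fertilization level. Conditions are
#' ranked by the mean R2 across indices. Per-condition ANOVA/Duncan letter
#' tables, the wavelength sensitivity table, simulated growth records and
#' their correlation report are included; everything is reproducible from
#' the config seed. Cubes whose segmentation or indices fail are logged and
#' skipped; the run aborts if more than half fail.
#'
#' @param config an [experiment_config()].
#' @return Object of class `ranking_result` with elements `vi` (long VI
#'   table), `r2` (R2 matrix in long form), `best_overall`, `best_per_index`,
#'   `dmrt_letters`, `sensitivity`, `growth`, `growth_r2`, `failures`,
#'   `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  sims <- .gather_cubes(config)
  params <- attr(sims, "params")
  if (is.null(params)) params <- config$params

  cubes <- lapply(sims, `[[`, "cube")
  n_total <- length(cubes)

  # segmentation + partition from the image itself
  labels <- vector("list", n_total)
  seg_fail <- character(0)
  for (i in seq_len(n_total)) {
    labels[[i]] <- tryCatch(
      partition_regions(segment_organ(cubes[[i]]), apex_end = "auto"),
      error = function(e) {
        seg_fail <<- c(seg_fail, sprintf("%s/%s/%g: %s", cubes[[i]]$plant_id,
                                         cubes[[i]]$organ, cubes[[i]]$angle,
                                         conditionMessage(e)))
        NULL
      })
  }
  keep <- !vapply(labels, is.null, logical(1))
  if (sum(keep) < n_total / 2) {
    stop(sprintf("more than half of the cubes failed segmentation (%d of %d)",
                 n_total - sum(keep), n_total), call. = FALSE)
  }
  vi <- batch_indices(cubes[keep], labels[keep], regions = config$regions)
  failures <- attr(vi, "failures")
  if (length(seg_fail)) {
    failures <- rbind(failures,
                      data.frame(cube = seg_fail, message = "segmentation failed",
                                 stringsAsFactors = FALSE))
  }

  # R2 matrix over (organ, region, angle, index)
  cells <- unique(vi[, c("organ", "region", "angle", "index")])
  r2 <- do.call(rbind, lapply(seq_len(nrow(cells)), function(r) {
    sub <- merge(vi, cells[r, , drop = FALSE])
    fit <- fit_vi_vs_rate(sub, params$design, config$predictor)
    cbind(cells[r, , drop = FALSE],
          data.frame(r2 = fit$r2, p = fit$p, stars = fit$stars, n = fit$n,
                     stringsAsFactors = FALSE))
  }))
  rownames(r2) <- NULL

  ranking <- rank_conditions(r2)

  # Duncan letter displays per condition (one table per organ/region/angle/index)
  key <- interaction(vi$organ, vi$region, vi$angle, vi$index, drop = TRUE)
  dmrt_letters <- do.call(rbind, lapply(split(vi, key), function(sub) {
    d <- dmrt(sub$value, sub$regime)
    cbind(sub[1, c("organ", "region", "angle", "index"), drop = FALSE],
          d$table, row.names = NULL)
  }))
  rownames(dmrt_letters) <- NULL

  # Table-1 style sensitivity table from regime-mean whole-organ spectra
  # (first configured angle)
  ang0 <- config$angles[1]
  sens_spectra <- list()
  for (org in config$organs) {
    for (regime in params$design$regime) {
      sel <- which(keep &
                     vapply(cubes, function(cc) {
                       identical(cc$organ, org) && identical(cc$regime, regime) &&
                         isTRUE(cc$angle == ang0)
                     }, logical(1)))
      if (!length(sel)) next
      sp <- lapply(sel, function(i) region_mean_spectrum(cubes[[i]], labels[[i]], "all"))
      refl <- Reduce(`+`, lapply(sp, `[[`, "reflectance")) / length(sp)
      s1 <- sp[[1]]; s1$reflectance <- refl; s1$plant_id <- NA_character_
      sens_spectra[[length(sens_spectra) + 1L]] <- s1
    }
  }
  sensitivity <- sd_proportion_table(sens_spectra)

  # growth records + correlation report
  growth <- simulate_growth_records(params, config$n_per_regime,
                                    seed = .cube_seed(config$seed, 999983L))
  growth_r2 <- growth_correlation_report(vi, growth)

  res <- structure(
    list(vi = vi, r2 = r2, best_overall = ranking$best_overall,
         best_per_index = ranking$best_per_index, ranking = ranking$mean_r2,
         dmrt_letters = dmrt_letters, sensitivity = sensitivity,
         growth = growth, growth_r2 = growth_r2, failures = failures,
         config = config),
    class = "ranking_result")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) utils::write.csv(
      df, file.path(config$out_dir, name), row.names = FALSE)
    wr(vi, "vi.csv"); wr(r2, "r2_matrix.csv")
    wr(dmrt_letters, "dmrt_letters.csv"); wr(sensitivity, "sensitivity.csv")
    wr(growth, "growth.csv"); wr(growth_r2, "growth_r2.csv")
    writeLines(utils::capture.output(print(res)),
               file.path(config$out_dir, "summary.txt"))
  }
  res
}

#' @export
print.ranking_result <- function(x, ...) {
  b <- x$best_overall
  cat(sprintf("Best overall condition: %s / %s / %g deg (mean R2 = %.3f%s)\n",
              b$organ, b$region, b$angle, b$mean_r2,
              if (isTRUE(b$tie)) " [tie]" else ""))
  cat("Best condition per index:\n")
  print(x$best_per_index, row.names = FALSE)
  invisible(x)
}

#' Rank acquisition conditions by coefficient of determination
#'
#' Per index, the best (organ, region, angle) cell is the R2 argmax; the
#' overall best condition maximizes the mean R2 across indices. Ties are
#' broken by organ (second_leaf, flag_leaf, spike), then region (apex to
#' base), then angle (105 before 125), and flagged.
#'
#' @param r2 long-form R2 table with columns `organ`, `region`, `angle`,
#'   `index`, `r2` (as produced by [run_experiment()]).
#' @return List with `best_overall` (one-row data.frame with `tie` flag),
#'   `best_per_index`, and `mean_r2` (the aggregated ranking table).
#' @export
rank_conditions <- function(r2) {
  if (is.null(r2) || !nrow(r2)) stop("empty R2 matrix", call. = FALSE)
  organ_rank <- match(r2$organ, c("second_leaf", "flag_leaf", "spike"))
  region_rank <- match(r2$region, REGION_NAMES)
  angle_rank <- rank(r2$angle)
  ord <- order(organ_rank, region_rank, r2$angle)
  r2o <- r2[ord, , drop = FALSE]

  pick <- function(df) {
    mx <- max(df$r2)
    hit <- which(df$r2 >= mx - 1e-12)
    out <- df[hit[1], , drop = FALSE]
    out$tie <- length(hit) > 1L
    out
  }
  best_per_index <- do.call(rbind, lapply(split(r2o, r2o$index), pick))
  rownames(best_per_index) <- NULL

  agg <- stats::aggregate(r2 ~ organ + region + angle, data = r2o, FUN = mean)
  names(agg)[names(agg) == "r2"] <- "mean_r2"
  agg <- agg[order(match(agg$organ, c("second_leaf", "flag_leaf", "spike")),
                   match(agg$region, REGION_NAMES), agg$angle), , drop = FALSE]
  mx <- max(agg$mean_r2)
  hit <- which(agg$mean_r2 >= mx - 1e-12)
  best_overall <- agg[hit[1], , drop = FALSE]
  best_overall$tie <- length(hit) > 1L
  rownames(best_overall) <- NULL
  rownames(agg) <- NULL
  list(best_overall = best_overall, best_per_index = best_per_index, mean_r2 = agg)
}

#' Correlate vegetation indices with growth traits
#'
#' For every (trait, organ, region, angle, index) cell, the OLS coefficient
#' of determination between the per-plant VI value and the plant's growth
#' trait, with significance stars.
#'
#' @param vi long VI table (needs `plant_id`, `organ`, `region`, `angle`,
#'   `index`, `value`).
#' @param growth growth table from [simulate_growth_records()] (or measured
#'   records with the same columns).
#' @param traits trait columns to correlate.
#' @return data.frame: trait, organ, region, angle, index, r2, p, stars, n.
#' @export
growth_correlation_report <- function(vi, growth,
                                      traits = c("height", "spad", "lai",
                                                 "leaf_n", "seed_weight")) {
  miss <- setdiff(unique(vi$plant_id), growth$plant_id)
  if (length(miss)) {
    stop("plant id(s) in VI table without growth record: ",
         paste(utils::head(miss, 10), collapse = ", "), call. = FALSE)
  }
  m <- merge(vi, growth, by = "plant_id")
  cells <- unique(m[, c("organ", "region", "angle", "index")])
  out <- list()
  for (r in seq_len(nrow(cells))) {
    sub <- merge(m, cells[r, , drop = FALSE])
    for (tr in traits) {
      # a trait with no variation has no defined R2; report NA, keep going
      fit <- tryCatch(.ols_r2(sub[[tr]], sub$value),
                      error = function(e) list(r2 = NA_real_, p = NA_real_,
                                               n = nrow(sub)))
      out[[length(out) + 1L]] <- cbind(
        data.frame(trait = tr, stringsAsFactors = FALSE),
        cells[r, , drop = FALSE],
        data.frame(r2 = fit$r2, p = fit$p, stars = p_stars(fit$p), n = fit$n,
                   stringsAsFactors = FALSE))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Box plot of vegetation-index values by regime
#'
#' Base-graphics box plot of one (organ, region, angle, index) cell, with
#' whiskers at the data minimum and maximum.
#'
#' @param vi long VI table.
#' @param organ,region,angle,index cell to plot.
#' @return Invisibly, the plotted subset.
#' @export
vi_boxplot <- function(vi, organ = "second_leaf", region = "base",
                       angle = 105, index = "GNDVI") {
  sub <- vi[vi$organ == organ & vi$region == region &
              vi$angle == angle & vi$index == index, ]
  if (!nrow(sub)) stop("no VI records for the requested cell", call. = FALSE)
  graphics::boxplot(value ~ regime, data = sub, range = 0,
                    main = sprintf("%s, %s of %s at %g deg", index, region, organ, angle),
                    xlab = "nitrogen regime", ylab = index)
  invisible(sub)
}
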