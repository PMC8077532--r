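#' Load and validate a pipeline configuration
#'
#' A run configuration can be an R list or a YAML/JSON file. Recognised
#' fields:
#' \describe{
#'   \item{animals}{list of animal entries: `path`, `animal_id`, `species`,
#'     `lineage_group`, optional `calibration` (default 1), `start_zt`
#'     (default 3), `frame_rate`.}
#'   \item{thresholds}{`speed` (cm/s, default 4), `min_rest_s` (default 60),
#'     `max_gap_s` (default 2).}
#'   \item{photoperiod}{`lights_on`, `lights_off`, `cycle_length`, `regime`.}
#'   \item{shelter}{optional zone: `type` ("rect"/"circle") plus bounds.}
#'   \item{tree}{optional Newick path.}
#'   \item{taxon_map}{optional named list: data taxon -> tree tip
#'     substitutions.}
#'   \item{morphometrics}{optional CSV path with columns `taxon`,
#'     `standard_length`, `eye_area`.}
#'   \item{territoriality}{optional CSV path with columns `taxon`, `group`
#'     for the phylogenetic ANOVA.}
#'   \item{stats}{`n_sims` (default 1000), `seed`.}
#' }
#'
#' @param config list, or path to a YAML/JSON file.
#' @return validated config list of class `cf_config`.
#' @export
read_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  config$thresholds <- utils::modifyList(
    list(speed = 4, min_rest_s = 60, max_gap_s = 2),
    config$thresholds %||% list())
  ppc <- utils::modifyList(
    list(lights_on = 0, lights_off = 14, cycle_length = 24,
         regime = "light_dark"),
    config$photoperiod %||% list())
  config$photoperiod <- photoperiod(ppc$lights_on, ppc$lights_off,
                                    ppc$cycle_length, ppc$regime)
  config$stats <- utils::modifyList(list(n_sims = 1000, seed = 1),
                                    config$stats %||% list())
  if (!is.null(config$shelter)) {
    sh <- config$shelter
    config$shelter <- if (identical(sh$type, "circle")) {
      zone_circle(sh$x, sh$y, sh$r)
    } else {
      zone_rect(sh$xmin, sh$xmax, sh$ymin, sh$ymax)
    }
  }
  for (f in c("tree", "morphometrics", "territoriality")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      abort(paste0("config path does not exist: ", f, " = ", config[[f]]))
    }
  }
  for (an in config$animals %||% list()) {
    if (is.null(an$path) || !file.exists(an$path)) {
      abort(paste0("tracking table missing for animal ",
                   an$animal_id %||% "<unnamed>", ": ", an$path %||% "<no path>"))
    }
  }
  structure(config, class = c("cf_config", "list"))
}

.log_line <- function(lines_env, msg) {
  line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", msg)
  lines_env$lines <- c(lines_env$lines, line)
  message(line)
}

#' Run the full chronotyping pipeline
#'
#' Orchestrates scoring, circadian metrics, the statistical battery and the
#' phylogenetic analyses from one config, writing every intermediate table
#' so each stage can be checked independently. Deterministic given the seed.
#' A failure on one animal is logged and skipped; the run continues.
#'
#' @param config a `cf_config`, list, or config file path (see
#'   [read_config()]).
#' @param outdir output directory; created if needed. `NULL` for no files.
#' @param stage one of `"score"`, `"circadian"`, `"stats"`, `"phylo"`,
#'   `"all"`: later stages imply the earlier ones.
#' @param seed overrides `config$stats$seed`.
#' @return list of result tables: `per_animal`, `bouts`, `species_summary`,
#'   `ar_tests`, `anova_tables`, `shelter`, `pgls`, `panova`, `qc`, `log`.
#' @export
run_pipeline <- function(config, outdir = NULL,
                         stage = c("all", "score", "circadian", "stats", "phylo"),
                         seed = NULL) {
  stage <- match.arg(stage)
  config <- read_config(config)
  seed <- seed %||% config$stats$seed
  set.seed(seed)
  lg <- new.env()
  lg$lines <- character(0)
  th <- config$thresholds
  pp <- config$photoperiod
  res <- list()
  stages_wanted <- switch(stage,
    score = "score",
    circadian = c("score", "circadian"),
    stats = c("score", "circadian", "stats"),
    phylo = c("score", "circadian", "phylo"),
    all = c("score", "circadian", "stats", "phylo"))

  # ---- score + circadian per animal -------------------------------------
  per_animal <- list()
  bouts_all <- list()
  for (an in config$animals %||% list()) {
    aid <- an$animal_id %||% basename(an$path)
    row <- tryCatch({
      traj <- read_tracking_table(
        an$path, calibration = an$calibration %||% 1, animal_id = aid,
        species = an$species %||% NA_character_,
        lineage_group = an$lineage_group %||% NA_character_,
        start_zt = an$start_zt %||% 3,
        frame_rate = an$frame_rate, arena = unlist(an$arena) %||% NULL)
      scored <- score_animal(traj, threshold = th$speed,
                             min_rest = th$min_rest_s, max_gap = th$max_gap_s)
      row <- scored$summary
      if ("circadian" %in% stages_wanted) {
        cm <- circadian_metrics(scored, traj = traj, pp = pp,
                                zone = config$shelter)
        row <- dplyr::bind_cols(row, cm[, setdiff(names(cm), names(row))])
      }
      if (nrow(scored$bouts) > 0) {
        bouts_all[[aid]] <- dplyr::mutate(scored$bouts, animal_id = aid,
                                          .before = 1)
      }
      if (row$frac_missing > 0.10) {
        .log_line(lg, sprintf("QC flag: %s has %.1f%% missing frames", aid,
                              100 * row$frac_missing))
      }
      .log_line(lg, sprintf("scored %s (%s): activity %.0f cm, rest %.2f h",
                            aid, row$species, row$total_activity_cm,
                            row$total_rest_h))
      row
    }, error = function(e) {
      .log_line(lg, sprintf("ERROR scoring %s: %s", aid, conditionMessage(e)))
      NULL
    })
    if (!is.null(row)) per_animal[[aid]] <- row
  }
  res$per_animal <- list_rbind(unname(per_animal))
  res$bouts <- if (length(bouts_all)) list_rbind(unname(bouts_all)) else
    tibble(animal_id = character(0), start_s = numeric(0),
           duration_s = numeric(0))

  if (nrow(res$per_animal) > 0 && "circadian" %in% stages_wanted) {
    res$species_summary <- res$per_animal |>
      group_by(.data$species, .data$lineage_group) |>
      summarise(n = dplyr::n(),
                across(c("total_activity_cm", "waking_velocity_cms",
                         "total_rest_h", dplyr::any_of(c("D", "N", "A_R"))),
                       ~ mean(.x, na.rm = TRUE)),
                .groups = "drop")
  }

  # ---- statistical battery ---------------------------------------------
  if ("stats" %in% stages_wanted && nrow(res$per_animal) > 0) {
    pa <- res$per_animal
    res$anova_tables <- list()
    safe <- function(name, expr) {
      tryCatch(expr, error = function(e) {
        .log_line(lg, sprintf("stats: skipped %s (%s)", name,
                              conditionMessage(e)))
        NULL
      })
    }
    if (length(unique(pa$species)) >= 2) {
      res$anova_tables$activity_species <-
        safe("one-way activity", one_way_anova(pa, total_activity_cm, species))
      res$anova_tables$waking_species <-
        safe("one-way waking velocity",
             one_way_anova(pa, waking_velocity_cms, species))
      res$anova_tables$rest_species <-
        safe("one-way rest", one_way_anova(pa, total_rest_h, species))
      res$anova_tables$levene_activity <-
        safe("Levene activity", levene_median_test(pa, total_activity_cm, species))
    }
    if (length(stats::na.omit(unique(pa$lineage_group))) == 2) {
      res$anova_tables$nested_activity <-
        safe("nested activity",
             nested_anova(pa, total_activity_cm, species, lineage_group))
      res$anova_tables$nested_rest <-
        safe("nested rest", nested_anova(pa, total_rest_h, species, lineage_group))
    }
    if ("A_R" %in% names(pa)) {
      res$ar_tests <- pa |>
        group_by(.data$species) |>
        dplyr::group_modify(function(d, key) {
          tryCatch(one_sample_ttest(d$A_R, 0), error = function(e) {
            tibble(estimate = mean(d$A_R, na.rm = TRUE), se = NA_real_,
                   statistic = NA_real_, df = NA_real_, p.value = NA_real_,
                   n = sum(!is.na(d$A_R)))
          })
        }) |>
        ungroup()
      .log_line(lg, sprintf("rhythmicity t-tests for %d species",
                            nrow(res$ar_tests)))
    }
    if (!is.null(config$shelter) && "occupancy_total" %in% names(pa)) {
      res$shelter <- pa |>
        select(dplyr::any_of(c("animal_id", "species", "occupancy_total",
                               "occupancy_day", "occupancy_night")))
      if (length(unique(pa$species)) >= 2) {
        res$anova_tables$shelter_species <-
          safe("one-way shelter", one_way_anova(pa, occupancy_total, species))
      }
    }
  }

  # ---- phylogenetic comparative analyses --------------------------------
  if ("phylo" %in% stages_wanted && !is.null(config$tree)) {
    tree <- read_newick(config$tree)
    if (!is.null(config$taxon_map)) {
      tree <- substitute_taxa(tree, unlist(config$taxon_map))
    }
    sp_traits <- if (!is.null(res$species_summary)) {
      filter(res$species_summary, .data$species %in% tree$tip.label)
    } else NULL
    res$pgls <- list()
    if (!is.null(config$morphometrics)) {
      morpho <- readr::read_csv(config$morphometrics, show_col_types = FALSE)
      morpho <- filter(morpho, .data$taxon %in% tree$tip.label)
      eye <- tryCatch(
        phylo_size_correct(morpho, tree),
        error = function(e) {
          .log_line(lg, paste0("phylo: size correction failed: ",
                               conditionMessage(e)))
          NULL
        })
      if (!is.null(eye) && !is.null(sp_traits) && nrow(sp_traits) >= 4) {
        dd <- dplyr::inner_join(eye, sp_traits,
                                by = c(taxon = "species"))
        res$eye_residuals <- eye
        res$pgls$eye_vs_rest <- tryCatch(
          pgls_fit(dd, residual_eye_area ~ total_rest_h, tree),
          error = function(e) NULL)
        res$pgls$eye_vs_ar <- tryCatch(
          pgls_fit(dd, residual_eye_area ~ A_R, tree),
          error = function(e) NULL)
        for (nm in names(res$pgls)) {
          f <- res$pgls[[nm]]
          if (!is.null(f)) {
            .log_line(lg, sprintf("PGLS %s: lambda %.3f R2 %.3f", nm,
                                  f$lambda, f$r.squared))
          }
        }
      }
    }
    if (!is.null(config$territoriality) && !is.null(sp_traits)) {
      terr <- readr::read_csv(config$territoriality, show_col_types = FALSE)
      dd <- dplyr::inner_join(sp_traits, terr, by = c(species = "taxon"))
      res$panova <- tryCatch(
        phylo_anova(dplyr::rename(dd, taxon = "species"),
                    total_activity_cm, group, tree,
                    n_sims = config$stats$n_sims, seed = seed),
        error = function(e) {
          .log_line(lg, paste0("phylo: pANOVA failed: ", conditionMessage(e)))
          NULL
        })
      if (!is.null(res$panova)) {
        .log_line(lg, sprintf("pANOVA: F %.3f p %.4f", res$panova$F_obs,
                              res$panova$p_phylo))
      }
    }
  }

  res$log <- lg$lines
  if (!is.null(outdir)) .write_bundle(res, outdir)
  res
}

# serialise the result bundle as CSV tables + JSON report + plain-text log
.write_bundle <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df) && is.data.frame(df) && nrow(df) > 0) {
      readr::write_csv(df, file.path(outdir, paste0(name, ".csv")))
    }
  }
  wr(res$per_animal, "per_animal")
  wr(res$bouts, "bouts")
  wr(res$species_summary, "species_summary")
  wr(res$ar_tests, "ar_tests")
  wr(res$shelter, "shelter")
  wr(res$eye_residuals, "eye_residuals")
  for (nm in names(res$anova_tables %||% list())) {
    wr(res$anova_tables[[nm]], paste0("anova_", nm))
  }
  report <- list()
  for (nm in names(res$pgls %||% list())) {
    f <- res$pgls[[nm]]
    if (!is.null(f)) {
      report$pgls[[nm]] <- c(as.list(glance(f)),
                             list(coefficients = as.list(f$coefficients)))
    }
  }
  if (!is.null(res$panova)) report$panova <- as.list(glance(res$panova))
  if (length(report) > 0) {
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  writeLines(res$log, file.path(outdir, "pipeline.log"))
  invisible(outdir)
}
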