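# End-to-end study orchestration: per-species modelling, per-pair
# overlap, and the cross-pair comparison, all driven by one config and
# one master seed.  Per-stage seeds are derived by stable hashing of
# (master seed, stage, species) so every stage is independently
# reproducible.

#' Default run configuration
#'
#' All tunable settings of the study pipeline with their standard
#' values: correlation threshold 0.7, key-factor cutoff 10 percent,
#' HSI class edges 0.25/0.50/0.75, overlap class edges
#' 0.2/0.4/0.6/0.8, RM grid 0.5-4 by 0.5 over the six feature-class
#' sets, 10000 background points, 15 replicates with a 0.75 training
#' fraction, post-hoc alpha 0.01.
#'
#' @param seed master seed.
#' @param ... overrides for any top-level entry.
#' @return config list.
#' @export
default_config <- function(seed = 1, ...) {
  cfg <- list(
    corr_threshold = 0.7,
    correlation_basis = "presence+background",
    key_factor_pct = 10.0,
    hsi_breaks = c(0.25, 0.5, 0.75),
    overlap_breaks = c(0.2, 0.4, 0.6, 0.8),
    rm_grid = seq(0.5, 4, by = 0.5),
    fc_sets = FC_SETS,
    n_background = 10000,
    n_replicates = 15,
    train_fraction = 0.75,
    alpha = 0.01,
    clamp = TRUE,
    latitude_weighted = FALSE,
    pilot_fc = "LQ",
    pilot_rm = 1,
    maxent = maxent_config(),
    seed = seed)
  ov <- list(...)
  for (nmv in names(ov)) cfg[[nmv]] <- ov[[nmv]]
  cfg
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config), f)
  unname(tools::md5sum(f))
}

write_csv_logged <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d", hash, seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# Valid-cell mask for modelling: all layers valid AND region mask == 1.
study_mask <- function(stack, mask = NULL) {
  m <- intersect_mask(stack)
  if (!is.null(mask)) m <- intersect_mask(m, as_mask(mask))
  m
}

#' Run the full per-species analysis
#'
#' Pipeline: spatial rarefaction on the current-climate lattice,
#' background draw, Pearson correlation filtering with pilot-model
#' contributions, AICc tuning over the RM x FC grid, replicate
#' fitting/evaluation, projection onto every scenario, suitability
#' classification and area summaries, the trend typology, and
#' key-factor identification (contribution above the configured
#' percentage).
#'
#' @param occ `enm_occurrences` for one species.
#' @param scenarios named list of `enm_stack`s; must include "current",
#'   every other entry is a future scenario (already
#'   ensemble-averaged; use [ensemble_mean()] for multi-member sets).
#' @param mask optional 0/1 region `enm_grid`.
#' @param config from [default_config()].
#' @param species label (default from `occ`).
#' @param out_dir optional directory for CSV / .asc artifacts.
#' @return an `enm_species_run` list (see fields in the implementation).
#' @export
run_species <- function(occ, scenarios, mask = NULL,
                        config = default_config(),
                        species = occ$species[1], out_dir = NULL) {
  if (!"current" %in% names(scenarios))
    stopf("scenarios must include an element named 'current'")
  current <- scenarios$current
  future_names <- setdiff(names(scenarios), "current")
  hash <- config_hash(config)
  stage_seed <- function(stage) derive_seed(config$seed, stage, species)

  # --- occurrences -> presence sample
  occ_r <- spatial_rarefy(occ, current[[1]])
  msk <- study_mask(current, mask)
  bg_cells <- sample_background(msk, config$n_background,
                                seed = stage_seed("background"))
  pres <- extract_values(current, occ_r, label = 1)
  bg <- extract_values(current, bg_cells, label = 0)
  if (nrow(pres) < 2) stopf("fewer than 2 usable presences after extraction")

  # --- variable selection
  vars0 <- stack_names(current)
  both <- rbind(pres, bg)
  corr <- pearson_matrix(both, basis = config$correlation_basis)
  contrib0 <- pilot_contributions(pres, bg, fc = config$pilot_fc,
                                  rm = config$pilot_rm)
  sel <- select_variables(corr, contrib0, threshold = config$corr_threshold)
  keep_cols <- c("cell", "label", sel$retained)
  pres_s <- pres[, keep_cols]
  bg_s <- bg[, keep_cols]

  # --- tuning on all presences
  cells_data <- extract_values(current, mask_cells(msk))[, sel$retained,
                                                         drop = FALSE]
  tuning <- tune_maxent(pres_s, bg_s, cells_data,
                        rm_grid = config$rm_grid,
                        fc_sets = config$fc_sets, config = config$maxent)

  # --- replicates
  splits <- split_replicates(nrow(pres_s), frac = config$train_fraction,
                             n_rep = config$n_replicates,
                             seed = stage_seed("splits"))
  reps <- fit_replicates(pres_s, bg_s, fc = tuning$selected$fc,
                         rm = tuning$selected$rm, splits = splits,
                         config = config$maxent)

  # --- per-scenario projection, evaluation, classification
  scen_out <- list()
  for (sc in names(scenarios)) {
    st <- scenarios[[sc]]
    agg <- aggregate_replicates(reps, st, clamp = config$clamp)
    # scenario-specific evaluation: replicate test presences and the
    # shared background, scored on this scenario's climate
    teb <- extract_values(st, bg_cells)
    ev <- lapply(seq_along(reps$models), function(r) {
      te_cells <- pres_s$cell[reps$splits[[r]]$test]
      tep <- extract_values(st, te_cells)
      spv <- predict_logistic(reps$models[[r]],
                              tep[, sel$retained, drop = FALSE],
                              clamp = config$clamp)
      sbv <- predict_logistic(reps$models[[r]],
                              teb[, sel$retained, drop = FALSE],
                              clamp = config$clamp)
      c(auc = eval_auc(spv, sbv), tss = eval_tss(spv, sbv)$tss)
    })
    ev <- do.call(rbind, ev)
    cls <- classify_suitability(agg$mean_map, breaks = config$hsi_breaks)
    area <- area_summary(cls, region_mask = msk, scenario = sc,
                         latitude_weighted = config$latitude_weighted)
    scen_out[[sc]] <- list(mean_map = agg$mean_map, class_map = cls,
                           area = area,
                           auc_mean = mean(ev[, "auc"]),
                           auc_sd = stats::sd(ev[, "auc"]),
                           tss_mean = mean(ev[, "tss"]),
                           tss_sd = stats::sd(ev[, "tss"]))
  }
  area_table <- do.call(rbind, lapply(scen_out, `[[`, "area"))
  rownames(area_table) <- NULL
  eval_table <- data.frame(
    scenario = names(scen_out),
    auc_mean = vapply(scen_out, `[[`, numeric(1), "auc_mean"),
    auc_sd = vapply(scen_out, `[[`, numeric(1), "auc_sd"),
    tss_mean = vapply(scen_out, `[[`, numeric(1), "tss_mean"),
    tss_sd = vapply(scen_out, `[[`, numeric(1), "tss_sd"),
    row.names = NULL, stringsAsFactors = FALSE)

  # --- typology over suitable percentages
  suit <- structure(area_table$pct_suitable, names = area_table$scenario)
  typology <- if (length(future_names) == 4)
    trend_typology(suit[["current"]], unname(suit[future_names]))
  else NULL

  # --- key climate factors from the tuned model on all presences
  vc <- variable_contribution(tuning$model, pres_s, bg_s,
                              config = config$maxent)
  contrib_table <- data.frame(
    variable = names(vc$contribution),
    contribution = as.numeric(vc$contribution),
    key_factor = as.numeric(vc$contribution) > config$key_factor_pct,
    stringsAsFactors = FALSE)
  contrib_table <- contrib_table[order(-contrib_table$contribution), ]
  rownames(contrib_table) <- NULL

  res <- structure(
    list(species = species, config_hash = hash, seed = config$seed,
         occurrences = occ_r, mask = msk, background_cells = bg_cells,
         selection = sel, tuning = tuning, replicates = reps,
         scenarios = scen_out, area_table = area_table,
         eval_table = eval_table, typology = typology,
         contributions = contrib_table,
         key_factors = contrib_table$variable[contrib_table$key_factor],
         jackknife = vc$jackknife),
    class = "enm_species_run")

  if (!is.null(out_dir)) write_species_artifacts(res, out_dir, config)
  res
}

write_species_artifacts <- function(res, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sp <- gsub("[^A-Za-z0-9_-]", "_", res$species)
  h <- res$config_hash; sd <- config$seed
  write_csv_logged(res$tuning$candidates,
                   file.path(out_dir, paste0(sp, "_tuning.csv")), h, sd)
  write_csv_logged(res$eval_table,
                   file.path(out_dir, paste0(sp, "_eval.csv")), h, sd)
  write_csv_logged(res$area_table,
                   file.path(out_dir, paste0(sp, "_area.csv")), h, sd)
  write_csv_logged(res$contributions,
                   file.path(out_dir, paste0(sp, "_contributions.csv")), h, sd)
  for (sc in names(res$scenarios)) {
    scn <- gsub("[^A-Za-z0-9_.-]", "_", sc)
    write_ascii_grid(res$scenarios[[sc]]$mean_map,
                     file.path(out_dir, sprintf("%s_%s_hsi.asc", sp, scn)))
    write_ascii_grid(res$scenarios[[sc]]$class_map,
                     file.path(out_dir, sprintf("%s_%s_class.asc", sp, scn)))
  }
  invisible(out_dir)
}

#' Parasite-host overlap analysis from two species runs
#'
#' Computes Schoener's D between the replicate-mean suitability maps of
#' the two species in every scenario, the overlap class per scenario,
#' the mean and sample SD, the overlap trend typology, and the
#' intersection of the two species' key climate factors.
#'
#' @param res_parasite,res_host `enm_species_run` objects sharing the
#'   same scenarios.
#' @param config from [default_config()].
#' @return an `enm_pair_run` list.
#' @export
run_pair <- function(res_parasite, res_host, config = default_config()) {
  scn <- names(res_parasite$scenarios)
  if (!identical(scn, names(res_host$scenarios)))
    stopf("species runs have different scenario sets")
  d <- vapply(scn, function(sc)
    schoener_d(res_parasite$scenarios[[sc]]$mean_map,
               res_host$scenarios[[sc]]$mean_map), numeric(1))
  future_names <- setdiff(scn, "current")
  summ <- pair_summary(unname(d))
  typ <- if (length(future_names) == 4)
    overlap_typology(d[["current"]], unname(d[future_names])) else NA
  structure(
    list(pair = c(parasite = res_parasite$species,
                  host = res_host$species),
         d = d, class_per_scenario = overlap_class(unname(d)),
         mean = summ$mean, sd = summ$sd, typology = typ,
         common_key_factors = intersect(res_parasite$key_factors,
                                        res_host$key_factors)),
    class = "enm_pair_run")
}

#' @export
print.enm_pair_run <- function(x, ...) {
  cat(sprintf("<enm_pair_run %s vs %s: D mean %.4f +/- %.4f (%s)>\n",
              x$pair[["parasite"]], x$pair[["host"]], x$mean, x$sd,
              x$typology))
  invisible(x)
}

#' Run the complete study
#'
#' All species, all parasite-host pairs, and (with two or more pairs)
#' the cross-pair one-way ANOVA with Tamhane T2 letters on the
#' per-scenario overlap values.
#'
#' @param occs named list of `enm_occurrences`, one per species.
#' @param pairs list of `c(parasite, host)` name pairs.
#' @param scenarios named list of `enm_stack`s including "current".
#' @param mask optional 0/1 region grid.
#' @param config from [default_config()].
#' @param out_dir optional artifact directory.
#' @return an `enm_study` list with `species`, `pairs`, `comparison`.
#' @export
run_study <- function(occs, pairs, scenarios, mask = NULL,
                      config = default_config(), out_dir = NULL) {
  species_res <- lapply(names(occs), function(sp)
    run_species(occs[[sp]], scenarios, mask = mask, config = config,
                species = sp, out_dir = out_dir))
  names(species_res) <- names(occs)
  pair_res <- lapply(pairs, function(pr) {
    if (!all(pr %in% names(species_res)))
      stopf("pair (%s) references unknown species", paste(pr, collapse = ", "))
    run_pair(species_res[[pr[1]]], species_res[[pr[2]]], config = config)
  })
  names(pair_res) <- vapply(pair_res, function(p)
    paste(p$pair, collapse = "-"), character(1))
  comparison <- NULL
  if (length(pair_res) >= 2) {
    groups <- lapply(pair_res, function(p) unname(p$d))
    comparison <- tamhane_t2(groups, alpha = config$alpha)
  }
  res <- structure(list(species = species_res, pairs = pair_res,
                        comparison = comparison,
                        config_hash = config_hash(config),
                        seed = config$seed),
                   class = "enm_study")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    h <- res$config_hash
    overlap_table <- do.call(rbind, lapply(pair_res, function(p)
      data.frame(pair = paste(p$pair, collapse = "-"),
                 scenario = names(p$d), d = unname(p$d),
                 class = p$class_per_scenario,
                 mean = p$mean, sd = p$sd, typology = p$typology,
                 common_key_factors = paste(p$common_key_factors,
                                            collapse = ";"),
                 stringsAsFactors = FALSE)))
    write_csv_logged(overlap_table, file.path(out_dir, "overlap.csv"),
                     h, config$seed)
    if (!is.null(comparison)) {
      write_csv_logged(comparison$pairwise,
                       file.path(out_dir, "posthoc_pairwise.csv"),
                       h, config$seed)
      write_csv_logged(
        data.frame(group = names(comparison$letters),
                   letter = unname(comparison$letters),
                   F = comparison$F, p = comparison$p,
                   stringsAsFactors = FALSE),
        file.path(out_dir, "posthoc_letters.csv"), h, config$seed)
    }
    manifest <- list(config_hash = h, seed = config$seed,
                     species = names(species_res),
                     pairs = names(pair_res),
                     artifacts = list.files(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

#' Simulate a complete in-memory study world
#'
#' Generates a current climate stack, four future scenarios (each the
#' equally-weighted ensemble of `n_members` perturbed members,
#' emulating GCM spread), a parasite-host truth pair with the given
#' niche offset, presence samples for both species, and an all-valid
#' region mask.
#'
#' @param nrows,ncols,K,range_len passed to [gen_climate_stack()].
#' @param n_presence presences per species.
#' @param offset_delta parasite-host niche offset.
#' @param n_members ensemble members per future scenario.
#' @param seed master seed.
#' @return list with `scenarios`, `occs`, `pairs`, `mask`, `truths`.
#' @export
simulate_world <- function(nrows = 100, ncols = 100, K = 8,
                           range_len = 10, n_presence = 200,
                           offset_delta = 0.5, n_members = 3,
                           seed = 1) {
  current <- gen_climate_stack(nrows, ncols, K = K,
                               range_len = range_len,
                               seed = derive_seed(seed, "climate"))
  scen_par <- list(
    "RCP2.6-2050s" = c(1.0, 1.03), "RCP8.5-2050s" = c(2.0, 1.06),
    "RCP2.6-2070s" = c(1.3, 1.04), "RCP8.5-2070s" = c(3.2, 1.09))
  scenarios <- list(current = current)
  for (sc in names(scen_par)) {
    members <- lapply(seq_len(n_members), function(mem)
      gen_future(current, warming_delta = scen_par[[sc]][1],
                 precip_scale = scen_par[[sc]][2],
                 seed = derive_seed(seed, "future", sc, mem)))
    scenarios[[sc]] <- ensemble_mean(members)
  }
  truths <- gen_pair(current, offset_delta = offset_delta)
  occs <- list(
    parasite = sample_presences(truths$parasite, n_presence,
                                seed = derive_seed(seed, "occ", "parasite")),
    host = sample_presences(truths$host, n_presence,
                            seed = derive_seed(seed, "occ", "host")))
  g0 <- current[[1]]
  mask <- as_mask(new_grid(rep(1, g0$nrows * g0$ncols), g0$nrows,
                           g0$ncols, g0$xll, g0$yll, g0$cellsize))
  list(scenarios = scenarios, occs = occs,
       pairs = list(c("parasite", "host")), mask = mask, truths = truths)
}

#' Write a simulated world to disk in the pipeline's input formats
#'
#' Emits one ESRI ASCII grid per layer per scenario member, the
#' occurrence CSV, the mask grid, and a JSON manifest listing scenario
#' membership.  [load_world()] reads it back (ensembling members).
#'
#' @param world from [simulate_world()]; already-ensembled scenario
#'   stacks are written as single-member scenarios.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(scenarios = list(), occurrences = "occurrences.csv",
                   mask = "mask.asc")
  for (sc in names(world$scenarios)) {
    scdir <- gsub("[^A-Za-z0-9_.-]", "_", sc)
    dir.create(file.path(dir, scdir), showWarnings = FALSE)
    st <- world$scenarios[[sc]]
    files <- character()
    for (v in stack_names(st)) {
      f <- file.path(scdir, paste0(v, ".asc"))
      write_ascii_grid(st[[v]], file.path(dir, f))
      files <- c(files, f)
    }
    manifest$scenarios[[sc]] <- list(members = list(files))
  }
  occ_all <- do.call(rbind, lapply(names(world$occs), function(sp) {
    o <- world$occs[[sp]]
    data.frame(species = sp, longitude = o$lon, latitude = o$lat,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(occ_all, file.path(dir, "occurrences.csv"),
                   row.names = FALSE)
  write_ascii_grid(world$mask, file.path(dir, "mask.asc"))
  manifest$pairs <- world$pairs
  jsonlite::write_json(manifest, file.path(dir, "world.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load a study world written by [write_world()]
#'
#' Multi-member scenarios are ensemble-averaged on load.
#'
#' @param dir directory holding `world.json`.
#' @return list with `scenarios`, `occs`, `pairs`, `mask`.
#' @export
load_world <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "world.json"),
                             simplifyVector = TRUE)
  read_stack_files <- function(files) {
    layers <- lapply(files, function(f) read_ascii_grid(file.path(dir, f)))
    names(layers) <- sub("\\.asc$", "", basename(files))
    raster_stack(layers)
  }
  scenarios <- lapply(man$scenarios, function(sc) {
    mem <- sc$members
    # JSON simplification can collapse a single member to a bare vector
    if (is.character(mem)) mem <- list(mem)
    if (is.matrix(mem)) mem <- split(mem, seq_len(nrow(mem)))
    members <- lapply(mem, function(fl) read_stack_files(unlist(fl)))
    if (length(members) > 1) ensemble_mean(members) else members[[1]]
  })
  occ_df <- utils::read.csv(file.path(dir, man$occurrences),
                            stringsAsFactors = FALSE)
  occs <- lapply(split(occ_df, occ_df$species), function(d)
    occurrences(d$species[1], d$longitude, d$latitude))
  pairs <- man$pairs
  if (is.matrix(pairs)) pairs <- split(pairs, seq_len(nrow(pairs)))
  list(scenarios = scenarios, occs = occs, pairs = pairs,
       mask = as_mask(read_ascii_grid(file.path(dir, man$mask))))
}
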