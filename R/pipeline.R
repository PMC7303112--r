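#' Per-chamber and per-animal fluxes from incubation tables
#'
#' Runs the closed-cell flux chain for every chamber: refill correction of
#' the start concentrations where the start sample was drawn from the
#' chamber itself, net release rates for DIC/DOC/POC, O2-regression
#' respiration (respiratory quotient applied), and tracer-C release for the
#' DIC and POC pools. Animal rates are then control-corrected in rate space
#' against the mean of the no-organism chambers of the same condition, and
#' standardized to tissue organic carbon.
#'
#' @param dataset List with `specimens`, `incubations`, `o2_series` and
#'   `batches` data.frames (the schemas written by [simulate_experiment()] /
#'   read by [read_tables()]).
#' @param config A [pipeline_config()] object.
#' @return List with `chambers` (raw per-chamber rates, umol h^-1, controls
#'   included) and `animals` (control-corrected rates plus standardized
#'   rates in umol C (mol OC)^-1 h^-1).
#' @export
compute_fluxes <- function(dataset, config = pipeline_config()) {
  inc <- dataset$incubations
  cst <- config$constants
  need <- c("chamber_id", "specimen_id", "role", "condition",
            "chamber_volume_l", "duration_h")
  stopifnot(all(need %in% names(inc)))

  rows <- lapply(seq_len(nrow(inc)), function(i) {
    r <- inc[i, ]
    start <- list(dic = r$dic_start_um, doc = r$doc_start_um,
                  poc = r$poc_start_um)
    if (identical(r$start_strategy, "self_with_refill")) {
      refill <- list(dic = r$refill_dic_um, doc = r$refill_doc_um,
                     poc = r$refill_poc_um)
      start <- lapply(names(start), function(p) {
        refill_corrected_start(start[[p]], refill[[p]],
                               r$refill_volume_l, r$chamber_volume_l)
      })
      names(start) <- c("dic", "doc", "poc")
    }
    o2s <- dataset$o2_series[dataset$o2_series$chamber_id == r$chamber_id, ]
    o2fit <- oxygen_consumption_rate(o2s$time_h, o2s$o2_um,
                                     r$chamber_volume_l)
    sb <- dataset$batches[
      dataset$batches$id == specimen_batch(dataset, r, inc), , drop = FALSE]
    f_sub <- sb$atom_fraction[1L]
    f_bg_dic <- background_fraction(r$dic_d13c_start, "dic", config)
    f_bg_poc <- background_fraction(r$poc_d13c_start, "poc", config)
    data.frame(
      chamber_id = r$chamber_id, specimen_id = r$specimen_id,
      role = r$role, condition = r$condition,
      respiration_total = respiration_from_oxygen(o2fit$rate, cst),
      o2_fit_r2 = o2fit$r_squared,
      doc_total = net_release_rate(start$doc, r$doc_end_um,
                                   r$chamber_volume_l, r$duration_h),
      poc_total = net_release_rate(start$poc, r$poc_end_um,
                                   r$chamber_volume_l, r$duration_h),
      respiration_tracer = tracer_release_rate(
        start$dic, r$dic_end_um, r$dic_d13c_start, r$dic_d13c_end,
        r$chamber_volume_l, r$duration_h, f_sub, f_bg_dic, cst),
      poc_tracer = tracer_release_rate(
        start$poc, r$poc_end_um, r$poc_d13c_start, r$poc_d13c_end,
        r$chamber_volume_l, r$duration_h, f_sub, f_bg_poc, cst),
      stringsAsFactors = FALSE)
  })
  chambers <- do.call(rbind, rows)

  qty <- c("respiration_total", "doc_total", "poc_total",
           "respiration_tracer", "poc_tracer")
  animals <- chambers[chambers$role == "animal", , drop = FALSE]
  for (cond in unique(animals$condition)) {
    ctrl <- chambers[chambers$role == "control" &
                       chambers$condition == cond, , drop = FALSE]
    sel <- animals$condition == cond
    for (q in qty) {
      animals[sel, q] <- control_corrected(animals[sel, q], ctrl[[q]])
    }
  }
  oc <- specimen_oc(dataset$specimens, config)
  animals$tissue_oc_mol <- oc[animals$specimen_id]
  for (q in qty) {
    animals[[paste0(q, "_std")]] <-
      standardize_to_biomass(animals[[q]], animals$tissue_oc_mol)
  }
  list(chambers = chambers, animals = animals)
}

# substrate batch id for a chamber: from the specimen for animal chambers,
# from any animal of the same condition for controls
specimen_batch <- function(dataset, row, inc) {
  sp <- dataset$specimens
  if (nzchar(row$specimen_id)) {
    return(sp$substrate_batch_id[sp$id == row$specimen_id][1L])
  }
  mates <- inc$specimen_id[inc$condition == row$condition &
                             inc$role == "animal"]
  sp$substrate_batch_id[sp$id %in% mates][1L]
}

background_fraction <- function(d13c_start, pool, config) {
  if (identical(config$background_strategy, "start_sample")) {
    NULL  # tracer_release_rate uses the start sample itself
  } else {
    delta_to_atom_fraction(config$fixed_background_delta13c[[pool]],
                           config$constants)
  }
}

# tissue OC per specimen, filling unmeasured values from the volume
# allometry where a displacement volume is available
specimen_oc <- function(specimens, config) {
  oc <- specimens$tissue_oc_mol
  fill <- is.na(oc) & !is.na(specimens$volume_ml)
  oc[fill] <- sponge_oc_from_volume(specimens$volume_ml[fill],
                                    log_base = config$log_base)
  stats::setNames(oc, specimens$id)
}

#' Tissue tracer incorporation for every fed specimen
#'
#' Per-taxon background delta-13C is the mean of the unfed conspecifics in
#' the specimen table; tissue OC is taken as measured or, where missing,
#' estimated from displacement volume via the sponge allometry. Reports the
#' standardized incorporation rate and the percentage of the provided tracer
#' carbon each animal took up (with the substrate-depletion warning above
#' 90%).
#'
#' @param dataset List with `specimens` and `batches`.
#' @param config A [pipeline_config()] object.
#' @return data.frame with one row per fed specimen: `specimen_id`, `taxon`,
#'   `substrate`, `tissue_oc_mol`, `incorporation_rate`
#'   (umol C (mol OC)^-1 h^-1), `tracer_c_umol`, `pct_of_provided`.
#' @export
compute_incorporation <- function(dataset, config = pipeline_config()) {
  sp <- dataset$specimens
  bg <- sp[sp$is_background, , drop = FALSE]
  bg_mean <- tapply(bg$tissue_delta13c, bg$taxon, mean)
  fed <- sp[!sp$is_background & nzchar(sp$substrate_batch_id), ,
            drop = FALSE]
  oc_all <- specimen_oc(sp, config)
  rows <- lapply(seq_len(nrow(fed)), function(i) {
    s <- fed[i, ]
    sb <- dataset$batches[dataset$batches$id == s$substrate_batch_id, ]
    if (nrow(sb) == 0L) {
      stop("dangling substrate_batch_id '", s$substrate_batch_id,
           "' for specimen ", s$id, call. = FALSE)
    }
    bgv <- if (!is.null(config$background_delta13c_override)) {
      config$background_delta13c_override
    } else {
      bg_mean[[s$taxon]]
    }
    if (is.null(bgv) || is.na(bgv)) {
      stop("missing background: no unfed conspecifics of taxon '", s$taxon,
           "'", call. = FALSE)
    }
    oc <- oc_all[[s$id]]
    res <- incorporation_rate(s$tissue_delta13c, bgv, oc, s$feeding_hours,
                              sb$atom_fraction, config$constants)
    provided <- sb$concentration_um * s$feeding_volume_l
    data.frame(specimen_id = s$id, taxon = s$taxon, substrate = sb$kind,
               tissue_oc_mol = oc,
               incorporation_rate = res$rate,
               tracer_c_umol = res$tracer_c_umol,
               pct_of_provided = percent_of_provided(res$tracer_c_umol,
                                                     provided),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble the full per-animal budget table
#'
#' Joins the control-corrected, biomass-standardized incubation fluxes with
#' the tissue incorporation rates and builds one budget row per animal
#' ([assemble_budget()]), plus the tissue-POC turnover
#' ([tissue_poc_turnover()]).
#'
#' @param fluxes Result of [compute_fluxes()].
#' @param incorporation Result of [compute_incorporation()].
#' @return data.frame, one row per animal, with taxon/substrate labels, all
#'   standardized fluxes, total turnover, tracer fractions and
#'   `poc_turnover_pct_day`.
#' @export
build_budget <- function(fluxes, incorporation) {
  an <- fluxes$animals
  rows <- lapply(seq_len(nrow(an)), function(i) {
    a <- an[i, ]
    inc <- incorporation[incorporation$specimen_id == a$specimen_id, ]
    if (nrow(inc) == 0L) {
      stop("no incorporation row for specimen ", a$specimen_id,
           call. = FALSE)
    }
    b <- assemble_budget(a$specimen_id,
                         a$respiration_total_std, a$poc_total_std,
                         a$doc_total_std,
                         inc$incorporation_rate,
                         a$respiration_tracer_std, a$poc_tracer_std)
    b$taxon <- inc$taxon
    b$substrate <- inc$substrate
    b$condition <- a$condition
    b$poc_turnover_pct_day <- tissue_poc_turnover(a$poc_total_std)
    b$pct_of_provided <- inc$pct_of_provided
    b
  })
  do.call(rbind, rows)
}

#' Run the whole analysis pipeline on one dataset
#'
#' Feeding incorporation, incubation fluxes, per-animal budget and the
#' nonparametric statistical battery, in the order the experiment imposes.
#' Deterministic given the inputs; all randomness in the package lives in
#' the simulators behind explicit seeds.
#'
#' @param dataset List of tables as from [read_tables()] or
#'   [simulate_experiment()].
#' @param config A [pipeline_config()] object.
#' @return List with `fluxes`, `incorporation`, `budget` and `stats`
#'   (comparisons of tracer fluxes across taxa and between substrates).
#' @examples
#' sim <- simulate_experiment(sim_config(seed = 3, n_animals_per_group = 3))
#' out <- run_pipeline(sim)
#' head(out$budget)
#' @export
run_pipeline <- function(dataset, config = pipeline_config()) {
  n_animals <- sum(dataset$incubations$role == "animal")
  if (n_animals == 0L) {
    warning("dataset contains only control chambers; budget is empty",
            call. = FALSE)
    return(list(fluxes = NULL, incorporation = NULL,
                budget = data.frame(), stats = data.frame()))
  }
  fluxes <- compute_fluxes(dataset, config)
  incorporation <- compute_incorporation(dataset, config)
  budget <- build_budget(fluxes, incorporation)
  stats_tabs <- lapply(
    c("incorporation_tracer", "respiration_tracer", "poc_tracer"),
    function(q) compare_flux_groups(budget, q, adjust = config$dunn_adjust))
  list(fluxes = fluxes, incorporation = incorporation, budget = budget,
       stats = do.call(rbind, stats_tabs))
}

#' Compare recovered rates with simulation ground truth
#'
#' Condition-level parameter recovery: for each taxon-substrate condition
#' the mean recovered rate of every quantity is ratioed against its true
#' value from the generator's ground-truth table.
#'
#' @param budget Budget table from [run_pipeline()] on a simulated dataset.
#' @param ground_truth `ground_truth` table from [simulate_experiment()].
#' @return data.frame with `condition`, `quantity`, `true`, `recovered`
#'   (condition mean) and `rel_error`.
#' @export
recovery_table <- function(budget, ground_truth) {
  map <- c(respiration_total = "respiration", poc_total = "poc_release",
           doc_total = "doc_release",
           incorporation_tracer = "incorporation",
           respiration_tracer = "respiration_tracer",
           poc_tracer = "poc_tracer")
  rows <- list()
  for (ci in seq_len(nrow(ground_truth))) {
    g <- ground_truth[ci, ]
    b <- budget[budget$condition == g$condition, , drop = FALSE]
    if (nrow(b) == 0L) next
    for (q in names(map)) {
      tr <- g[[map[[q]]]]
      rec <- mean(b[[q]])
      rows[[length(rows) + 1L]] <- data.frame(
        condition = g$condition, quantity = q, true = tr, recovered = rec,
        rel_error = if (tr != 0) (rec - tr) / tr else rec,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
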