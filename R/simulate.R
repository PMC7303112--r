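#' Configuration for a synthetic tracer-feeding experiment
#'
#' Defines the ground truth and design of a simulated pulse-chase experiment:
#' three suspension-feeder taxa (a bivalve, a high-microbial-abundance sponge
#' and a low-microbial-abundance sponge) are each fed a 13C-labelled
#' substrate (DOM or bacteria), then closed-cell incubated. Defaults mirror
#' the study design the package analyses: 4 animals and 2 no-organism
#' controls per taxon-substrate condition, 4.8 L feeding chambers, DOM at
#' 239 uM C (atom fraction 0.25) and bacteria at 34.5 uM C (atom fraction
#' 0.955), taxon-specific feeding/incubation durations, and incubations
#' stopped well above 80% O2 saturation.
#'
#' True rates are in umol C (mol OC)^-1 h^-1 and must be >= 0. Measurement
#' noise is independent additive Gaussian at each sampling point, with
#' standard deviations set to typical analytical replicate precision
#' (DIC 1.5 uM, DOC 0.5 uM, POC 0.1 uM, delta-13C 0.2 per-mil, O2 0.5 uM).
#'
#' @param seed Integer seed; the same seed and config give identical output.
#' @param n_animals_per_group Animals per taxon-substrate condition.
#' @param n_controls No-organism control chambers per condition.
#' @param n_background Unfed background specimens per taxon.
#' @param taxa data.frame of per-taxon design and true rates; see
#'   `default_taxa()` for the columns and default values.
#' @param substrates data.frame with columns `id`, `kind`, `concentration_um`
#'   and `atom_fraction` describing the labelled substrate batches.
#' @param tracer_fraction_released Named list: the fraction of released DIC
#'   (`dic`) and POC (`poc`) carbon that is substrate-derived.
#' @param noise Named list of Gaussian noise standard deviations:
#'   `dic_sd`, `doc_sd`, `poc_sd` (uM), `delta_sd` (per-mil), `o2_sd` (uM),
#'   `foodchain_rel_sd` (relative).
#' @param ambient Named list of ambient concentrations: `dic`, `doc`, `poc`
#'   (uM) and `o2_saturation_um`.
#' @param refill Named list of refill-water concentrations for the
#'   self-with-refill start strategy: `dic`, `doc`, `poc` (uM).
#' @param background_delta13c Named list of background delta-13C (per-mil)
#'   for `dic`, `doc`, `poc` pools and animal `tissue`.
#' @param o2_saturation_min Fraction of saturation below which a simulated
#'   incubation is rejected as infeasible (default 0.8).
#' @param o2_log_interval_h O2 logger sampling interval, h.
#' @param foodchain Named list configuring the (pseudo-)feces transfer
#'   experiment: `n_bivalves`, `n_ophiuroids`, `n_cycles`,
#'   `daily_supply_umol_c` (fecal C offered per ophiuroid per cycle),
#'   `true_transfer_efficiency` (percent), `fecal_excess13c_fraction`
#'   (excess 13C per unit fecal C).
#' @param constants An [iso_constants()] object.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_animals_per_group = 4L,
                       n_controls = 2L,
                       n_background = 3L,
                       taxa = default_taxa(),
                       substrates = default_substrates(),
                       tracer_fraction_released = list(dic = 0.04,
                                                       poc = 0.02),
                       noise = list(dic_sd = 1.5, doc_sd = 0.5,
                                    poc_sd = 0.1, delta_sd = 0.2,
                                    o2_sd = 0.5, foodchain_rel_sd = 0.08),
                       ambient = list(dic = 2150, doc = 73.5, poc = 5,
                                      o2_saturation_um = 320),
                       refill = list(dic = 2140, doc = 70, poc = 2),
                       background_delta13c = list(dic = 0.5, doc = -22,
                                                  poc = -24, tissue = -20),
                       o2_saturation_min = 0.8,
                       o2_log_interval_h = 0.5,
                       foodchain = list(n_bivalves = 2L, n_ophiuroids = 4L,
                                        n_cycles = 4L,
                                        daily_supply_umol_c = 7.2,
                                        true_transfer_efficiency = 37,
                                        fecal_excess13c_fraction = 0.28),
                       constants = iso_constants()) {
  rate_cols <- c("respiration", "poc_release", "doc_release",
                 "incorporation")
  stopifnot(is.data.frame(taxa), all(rate_cols %in% names(taxa)),
            is.data.frame(substrates))
  if (any(as.matrix(taxa[rate_cols]) < 0)) {
    stop("all true rates must be >= 0", call. = FALSE)
  }
  nz <- unlist(noise)
  if (any(nz < 0)) stop("noise standard deviations must be >= 0",
                        call. = FALSE)
  if (any(substrates$atom_fraction <= 0 | substrates$atom_fraction > 1)) {
    stop("substrate atom fractions must lie in (0, 1]", call. = FALSE)
  }
  if (foodchain$true_transfer_efficiency < 0) {
    stop("true transfer efficiency must be >= 0", call. = FALSE)
  }
  structure(list(seed = as.integer(seed),
                 n_animals_per_group = as.integer(n_animals_per_group),
                 n_controls = as.integer(n_controls),
                 n_background = as.integer(n_background),
                 taxa = taxa, substrates = substrates,
                 tracer_fraction_released = tracer_fraction_released,
                 noise = noise, ambient = ambient, refill = refill,
                 background_delta13c = background_delta13c,
                 o2_saturation_min = o2_saturation_min,
                 o2_log_interval_h = o2_log_interval_h,
                 foodchain = foodchain, constants = constants),
            class = "sim_config")
}

#' Default per-taxon design and true rates
#'
#' One row per taxon with the chamber geometry, exposure durations, tissue
#' organic-carbon range (mol) and true flux rates
#' (umol C (mol OC)^-1 h^-1). The sponge taxon with the self-with-refill
#' start strategy is also the one whose tissue OC is estimated from body
#' volume by allometry rather than measured (`oc_from_volume = TRUE`).
#'
#' @return data.frame of taxon parameters.
#' @export
default_taxa <- function() {
  data.frame(
    taxon = c("bivalve", "hma_sponge", "lma_sponge"),
    feeding_volume_l = c(4.8, 4.8, 4.8),
    incubation_volume_l = c(4.8, 4.8, 1.3),
    feeding_hours = c(12.5, 6.2, 7.4),
    incubation_hours = c(11.0, 5.8, 5.4),
    oc_min = c(0.08, 0.08, 0.012),
    oc_max = c(0.16, 0.20, 0.024),
    respiration = c(150, 120, 400),
    poc_release = c(45, 20, 100),
    doc_release = c(60, 100, 200),
    incorporation = c(60, 80, 50),
    start_strategy = c("separate_chamber", "separate_chamber",
                       "self_with_refill"),
    refill_volume_l = c(0, 0, 0.5),
    oc_from_volume = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Default labelled substrate batches
#'
#' DOM and bacteria batches used in the feeding experiment plus the diatom
#' batch used in the (pseudo-)feces transfer experiment, with feeding-chamber
#' carbon concentrations (uM C) and 13C atom fractions inside the measured
#' batch ranges (DOM 0.244-0.255, bacteria 0.947-0.965, diatoms 0.292).
#'
#' @return data.frame of substrate batches.
#' @export
default_substrates <- function() {
  data.frame(
    id = c("dom_b1", "bacteria_b1", "diatom_b1"),
    kind = c("dom", "bacteria", "diatom"),
    concentration_um = c(239, 34.5, 300),
    atom_fraction = c(0.250, 0.955, 0.292),
    stringsAsFactors = FALSE
  )
}

# inverse of the sponge OC allometry: displacement volume (mL) whose
# predicted OC equals `oc` mol
volume_from_oc <- function(oc, log_base = 10, oc_fraction = 0.5) {
  log_base^(oc * 12.011 / (oc_fraction * 0.265))
}

#' Simulate a complete tracer-feeding experiment
#'
#' Forward model of the feeding + closed-cell-incubation design: tissue
#' enrichment accrues linearly at the true incorporation rate during
#' feeding (capped at the provided substrate carbon, with a depletion
#' warning); during the incubation every pool accumulates linearly at the
#' true flux, the delta-13C of the accumulating DIC and POC follows from
#' mixing background carbon with substrate-derived carbon, and the O2 series
#' declines linearly at the respiration rate (respiratory quotient applied).
#' Controls hold zero true flux. Gaussian measurement noise is added at each
#' sampling point; with all noise standard deviations zero the analysis
#' pipeline recovers every true rate exactly.
#'
#' @param config A [sim_config()] object.
#' @return List of data.frames: `specimens`, `batches`, `incubations`,
#'   `o2_series`, `ground_truth` — the same tables [read_tables()] accepts.
#' @examples
#' sim <- simulate_experiment(sim_config(seed = 42, n_animals_per_group = 2))
#' head(sim$incubations)
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cst <- config$constants
  nz <- config$noise
  amb <- config$ambient
  bgd <- config$background_delta13c
  f_bg <- lapply(bgd, delta_to_atom_fraction, constants = cst)
  subs <- config$substrates[config$substrates$kind %in%
                              c("dom", "bacteria"), ]

  specimens <- list(); incs <- list(); o2 <- list(); truth <- list()
  chamber_counter <- 0L

  # unfed background conspecifics, one set per taxon
  for (ti in seq_len(nrow(config$taxa))) {
    tx <- config$taxa[ti, ]
    for (b in seq_len(config$n_background)) {
      specimens[[length(specimens) + 1L]] <- data.frame(
        id = sprintf("%s_bg%d", tx$taxon, b), taxon = tx$taxon,
        volume_ml = NA_real_, tissue_oc_mol = NA_real_,
        dry_mass_g = NA_real_,
        tissue_delta13c = bgd$tissue + stats::rnorm(1, 0, nz$delta_sd),
        is_background = TRUE, substrate_batch_id = "",
        feeding_hours = NA_real_, feeding_volume_l = NA_real_,
        stringsAsFactors = FALSE)
    }
  }

  for (ti in seq_len(nrow(config$taxa))) {
    tx <- config$taxa[ti, ]
    for (si in seq_len(nrow(subs))) {
      sb <- subs[si, ]
      cond <- paste(tx$taxon, sb$kind, sep = "_")
      provided_c <- sb$concentration_um * tx$feeding_volume_l  # umol
      truth[[length(truth) + 1L]] <- data.frame(
        condition = cond, taxon = tx$taxon, substrate = sb$kind,
        respiration = tx$respiration, poc_release = tx$poc_release,
        doc_release = tx$doc_release, incorporation = tx$incorporation,
        respiration_tracer =
          tx$respiration * config$tracer_fraction_released$dic,
        poc_tracer = tx$poc_release * config$tracer_fraction_released$poc,
        stringsAsFactors = FALSE)

      for (a in seq_len(config$n_animals_per_group + config$n_controls)) {
        is_control <- a > config$n_animals_per_group
        chamber_counter <- chamber_counter + 1L
        chamber_id <- sprintf("ch%03d", chamber_counter)
        vol <- tx$incubation_volume_l
        dur <- tx$incubation_hours

        if (!is_control) {
          sp_id <- sprintf("%s_%s_%d", tx$taxon, sb$kind, a)
          oc <- stats::runif(1, tx$oc_min, tx$oc_max)
          # feeding phase: tissue tracer accrual, capped by supply
          inc_c <- tx$incorporation * oc * tx$feeding_hours  # umol tracer C
          if (inc_c > provided_c) {
            warning(sprintf(
              "substrate depleted during feeding for %s: %.1f of %.1f umol ",
              sp_id, inc_c, provided_c), "tracer C; incorporation capped",
              call. = FALSE)
            inc_c <- provided_c
          }
          excess_tissue <- inc_c * sb$atom_fraction  # umol 13C
          f_tis <- f_bg$tissue + excess_tissue / (oc * 1e6)
          d_tis <- atom_fraction_to_delta(f_tis, cst) +
            stats::rnorm(1, 0, nz$delta_sd)
          specimens[[length(specimens) + 1L]] <- data.frame(
            id = sp_id, taxon = tx$taxon,
            volume_ml = if (tx$oc_from_volume) volume_from_oc(oc)
                        else NA_real_,
            tissue_oc_mol = if (tx$oc_from_volume) NA_real_ else oc,
            dry_mass_g = NA_real_,
            tissue_delta13c = d_tis, is_background = FALSE,
            substrate_batch_id = sb$id, feeding_hours = tx$feeding_hours,
            feeding_volume_l = tx$feeding_volume_l,
            stringsAsFactors = FALSE)
          raw <- list(resp = tx$respiration * oc,
                      poc = tx$poc_release * oc,
                      doc = tx$doc_release * oc,
                      tr_resp = tx$respiration *
                        config$tracer_fraction_released$dic * oc,
                      tr_poc = tx$poc_release *
                        config$tracer_fraction_released$poc * oc)
        } else {
          sp_id <- ""
          raw <- list(resp = 0, poc = 0, doc = 0, tr_resp = 0, tr_poc = 0)
        }

        # effective start concentrations after the (possible) refill
        w <- tx$refill_volume_l / vol
        eff_start <- list(
          dic = amb$dic * (1 - w) + config$refill$dic * w,
          doc = amb$doc * (1 - w) + config$refill$doc * w,
          poc = amb$poc * (1 - w) + config$refill$poc * w)
        end <- list(dic = eff_start$dic + raw$resp * dur / vol,
                    doc = eff_start$doc + raw$doc * dur / vol,
                    poc = eff_start$poc + raw$poc * dur / vol)
        # mass conservation of the forward model (pre-noise)
        stopifnot(all(abs(end$doc - eff_start$doc - raw$doc * dur / vol)
                      < 1e-9))
        for (pool in names(end)) {
          if (end[[pool]] <= 0) {
            stop(sprintf(
              "infeasible design: pool '%s' exhausted in chamber %s",
              pool, chamber_id), call. = FALSE)
          }
        }
        # isotope signal of the accumulating pools
        e_dic <- raw$tr_resp * sb$atom_fraction * dur   # umol excess 13C
        e_poc <- raw$tr_poc * sb$atom_fraction * dur
        f_dic_end <- f_bg$dic + e_dic / (end$dic * vol)
        f_poc_end <- f_bg$poc + e_poc / (end$poc * vol)

        d <- function(f) atom_fraction_to_delta(f, cst)
        n1 <- function(sd) stats::rnorm(1, 0, sd)
        incs[[length(incs) + 1L]] <- data.frame(
          chamber_id = chamber_id, specimen_id = sp_id,
          role = if (is_control) "control" else "animal",
          condition = cond,
          chamber_volume_l = vol, duration_h = dur,
          dic_start_um = amb$dic + n1(nz$dic_sd),
          dic_end_um = end$dic + n1(nz$dic_sd),
          dic_d13c_start = bgd$dic + n1(nz$delta_sd),
          dic_d13c_end = d(f_dic_end) + n1(nz$delta_sd),
          doc_start_um = amb$doc + n1(nz$doc_sd),
          doc_end_um = end$doc + n1(nz$doc_sd),
          poc_start_um = amb$poc + n1(nz$poc_sd),
          poc_end_um = end$poc + n1(nz$poc_sd),
          poc_d13c_start = bgd$poc + n1(nz$delta_sd),
          poc_d13c_end = d(f_poc_end) + n1(nz$delta_sd),
          start_strategy = tx$start_strategy,
          refill_volume_l = tx$refill_volume_l,
          refill_dic_um = config$refill$dic + n1(nz$dic_sd),
          refill_doc_um = config$refill$doc + n1(nz$doc_sd),
          refill_poc_um = config$refill$poc + n1(nz$poc_sd),
          stringsAsFactors = FALSE)

        # O2 series: linear decline at the respiration rate
        times <- seq(0, dur, by = config$o2_log_interval_h)
        o2_true <- amb$o2_saturation_um -
          (raw$resp / cst$respiratory_quotient) / vol * times
        floor_um <- config$o2_saturation_min * amb$o2_saturation_um
        if (min(o2_true) < floor_um) {
          stop(sprintf(
            "infeasible design: O2 in chamber %s drops below %.0f%% %s",
            chamber_id, 100 * config$o2_saturation_min, "saturation"),
            call. = FALSE)
        }
        o2[[length(o2) + 1L]] <- data.frame(
          chamber_id = chamber_id, specimen_id = sp_id,
          time_h = times,
          o2_um = o2_true + stats::rnorm(length(times), 0, nz$o2_sd),
          stringsAsFactors = FALSE)
      }
    }
  }

  batches <- config$substrates
  names(batches) <- c("id", "kind", "concentration_um", "atom_fraction")
  list(specimens = do.call(rbind, specimens),
       batches = batches,
       incubations = do.call(rbind, incs),
       o2_series = do.call(rbind, o2),
       ground_truth = do.call(rbind, truth))
}

#' Simulate the (pseudo-)feces transfer experiment
#'
#' Forward model of the bivalve-to-ophiuroid food chain: over `n_cycles`
#' daily cycles the producers generate labelled (pseudo-)fecal droppings
#' that are offered to the consumers, whose pooled tissue incorporation over
#' the whole experiment realizes the configured transfer efficiency exactly
#' before noise. Multiplicative Gaussian noise perturbs each measured pool.
#'
#' @param config A [sim_config()] object.
#' @return List with `foodchain` (columns `producer_ids`, `consumer_ids`,
#'   `pool` in fecal/tissue, `cycle`, `excess_13c_umol`, `period_d`) and
#'   `ground_truth`.
#' @examples
#' fc <- simulate_food_chain(sim_config(seed = 7))
#' estimate_transfer_efficiency(fc$foodchain)
#' @export
simulate_food_chain <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  fc <- config$foodchain
  rel <- config$noise$foodchain_rel_sd
  producers <- paste0("biv", seq_len(fc$n_bivalves), collapse = "|")
  consumers <- paste0("oph", seq_len(fc$n_ophiuroids))

  fecal_true <- fc$n_ophiuroids * fc$daily_supply_umol_c *
    fc$fecal_excess13c_fraction          # umol 13C per cycle, all chambers
  rows <- list()
  for (cyc in seq_len(fc$n_cycles)) {
    rows[[length(rows) + 1L]] <- data.frame(
      producer_ids = producers, consumer_ids = "",
      pool = "fecal", cycle = cyc,
      excess_13c_umol = fecal_true * (1 + stats::rnorm(1, 0, rel)),
      period_d = 1, stringsAsFactors = FALSE)
  }
  tissue_per_oph <- fc$true_transfer_efficiency / 100 *
    fecal_true * fc$n_cycles / fc$n_ophiuroids
  for (oph in consumers) {
    rows[[length(rows) + 1L]] <- data.frame(
      producer_ids = producers, consumer_ids = oph,
      pool = "tissue", cycle = NA_integer_,
      excess_13c_umol = tissue_per_oph * (1 + stats::rnorm(1, 0, rel)),
      period_d = fc$n_cycles, stringsAsFactors = FALSE)
  }
  list(foodchain = do.call(rbind, rows),
       ground_truth = data.frame(
         true_transfer_efficiency = fc$true_transfer_efficiency,
         total_supply_umol_c = daily_supply_total(fc$daily_supply_umol_c,
                                                  fc$n_cycles),
         stringsAsFactors = FALSE))
}

#' Transfer efficiency from a food-chain table
#'
#' Sums the fecal and consumer-tissue excess-13C pools of a food-chain table
#' and ratios them with [transfer_efficiency()].
#'
#' @param foodchain data.frame as produced by [simulate_food_chain()] or
#'   read from `foodchain.csv`, with columns `pool` and `excess_13c_umol`.
#' @return Transfer efficiency in percent.
#' @export
estimate_transfer_efficiency <- function(foodchain) {
  stopifnot(all(c("pool", "excess_13c_umol") %in% names(foodchain)))
  fecal <- sum(foodchain$excess_13c_umol[foodchain$pool == "fecal"])
  tissue <- sum(foodchain$excess_13c_umol[foodchain$pool == "tissue"])
  transfer_efficiency(fecal, tissue)
}
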