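# Synthetic longitudinal multi-reactor OTU datasets with planted
# core/intermediate/transient labels and two digestion systems (agricultural
# and bio-waste "AD" versus wastewater "WWTP") carrying largely distinct
# cores. The generative model is Dirichlet-multinomial around reactor
# profiles with AR(1) month-to-month drift, so every downstream stage of the
# pipeline can be exercised and scored against known truth.

#' Specification of a synthetic reactor survey
#'
#' Defaults emulate the monitored study design: 20 reactors in four categories
#' sampled monthly for a year, ~6,000 OTUs of which 2.5\% are core carrying
#' 70\% of reads and 84\% are transient carrying ~3.5\%, bacterial depth
#' 11,550. Core and intermediate OTUs are system-specific with a small shared
#' fraction; transients appear per sample as independent Bernoulli events at
#' low abundance.
#'
#' @param n_reactors number of reactors (>= 4; both systems populated).
#' @param n_timepoints monthly timepoints per reactor.
#' @param n_otus total OTUs.
#' @param core_fraction fraction of OTUs planted core.
#' @param transient_fraction fraction planted transient (rest intermediate).
#' @param target_core_share expected read share of the core pool per sample.
#' @param transient_share expected read share of transients per sample.
#' @param shared_core_between_systems fraction of core (and intermediate) OTUs
#'   shared by both systems.
#' @param transient_occurrence_rate per-sample Bernoulli presence rate of each
#'   transient OTU.
#' @param depth reads per sample.
#' @param overdispersion total Dirichlet concentration; lower = noisier
#'   replicate samples. The default (600) puts within-reactor Bray-Curtis
#'   around 0.2-0.3.
#' @param temporal_autocorrelation AR(1) coefficient in [0, 1) for
#'   month-to-month drift of the latent composition.
#' @param core_min_abundance floor on a core OTU's expected relative
#'   abundance, keeping planted cores detectable at the working depths.
#' @param intermediate_min_abundance floor on an intermediate OTU's expected
#'   relative abundance within the reactors where it is present.
#' @param turnover_reactors reactor acronyms generated with no temporal
#'   autocorrelation and strongly reduced concentration (high monthly
#'   turnover), for stability contrasts.
#' @param turnover_concentration Dirichlet concentration used for turnover
#'   reactors.
#' @param domain amplicon domain tag for the generated table.
#' @param seed RNG seed; identical spec + seed gives a bit-identical dataset.
#' @return An object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_reactors = 20L,
                           n_timepoints = 12L,
                           n_otus = 6000L,
                           core_fraction = 0.025,
                           transient_fraction = 0.84,
                           target_core_share = 0.70,
                           transient_share = 0.035,
                           shared_core_between_systems = 0.1,
                           transient_occurrence_rate = 0.02,
                           depth = 11550L,
                           overdispersion = 600,
                           temporal_autocorrelation = 0.3,
                           core_min_abundance = 0.002,
                           intermediate_min_abundance = 0.00105,
                           turnover_reactors = NULL,
                           turnover_concentration = 30,
                           domain = c("bacteria", "archaea"),
                           seed = 1L) {
  domain <- match.arg(domain)
  fr <- c(core_fraction, transient_fraction, target_core_share, transient_share,
          shared_core_between_systems, transient_occurrence_rate)
  if (any(fr < 0) || any(fr > 1)) stop("fractions must lie in [0,1]", call. = FALSE)
  if (core_fraction + transient_fraction > 1) {
    stop("core_fraction + transient_fraction must be <= 1", call. = FALSE)
  }
  if (target_core_share + transient_share > 1) {
    stop("target_core_share + transient_share must be <= 1", call. = FALSE)
  }
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (n_reactors < 4L) stop("need at least 4 reactors (both systems)", call. = FALSE)
  if (temporal_autocorrelation < 0 || temporal_autocorrelation >= 1) {
    stop("temporal_autocorrelation must lie in [0,1)", call. = FALSE)
  }
  n_core <- round(core_fraction * n_otus)
  if (target_core_share > 0 && n_core == 0) {
    stop("infeasible: positive target_core_share with zero core OTUs", call. = FALSE)
  }
  inter_share <- 1 - target_core_share - transient_share
  n_inter <- n_otus - n_core - round(transient_fraction * n_otus)
  if (inter_share > 0 && n_inter == 0) {
    stop("infeasible: positive intermediate share with zero intermediate OTUs",
         call. = FALSE)
  }
  spec <- as.list(environment())
  structure(spec, class = "synthetic_spec")
}

# Reactor layout. For 20 reactors this mirrors the monitored survey: 2 farm,
# 12 bio-waste, 3 MSW and 3 WWTP reactors over 10 biogas units; other sizes
# are allocated proportionally.
#' @noRd
make_reactor_layout <- function(n_reactors) {
  if (n_reactors == 20L) {
    data.frame(
      reactor = c("B", "C",
                  "BKA", "BKB", "BKC", "BKD", "BKE",
                  "FR1", "FR2", "FR3", "MbioA", "MbioB", "MbioC", "NK",
                  "MK-beg", "MK-mid", "MK-end",
                  "P", "S", "BT"),
      unit = c("U-1", "U-2",
               rep("U-3", 5), rep("U-4", 3), rep("U-5", 3), "U-6",
               rep("U-7", 3),
               "U-8", "U-9", "U-10"),
      category = c(rep("farm", 2), rep("bio-waste", 12), rep("MSW", 3),
                   rep("WWTP-AD", 3)),
      stringsAsFactors = FALSE
    )
  } else {
    n_wwtp <- max(2L, round(0.15 * n_reactors))
    n_farm <- max(1L, round(0.10 * n_reactors))
    n_msw <- max(1L, round(0.15 * n_reactors))
    n_bio <- n_reactors - n_wwtp - n_farm - n_msw
    if (n_bio < 1L) stop("too few reactors to populate all categories", call. = FALSE)
    cats <- c(rep("farm", n_farm), rep("bio-waste", n_bio), rep("MSW", n_msw),
              rep("WWTP-AD", n_wwtp))
    data.frame(
      reactor = sprintf("R%02d", seq_len(n_reactors)),
      unit = sprintf("U-%d", cumsum(!duplicated(cats)) + seq_along(cats) %/% 3L),
      category = cats, stringsAsFactors = FALSE
    )
  }
}

# Scale weights to a total share with a per-OTU floor; falls back to plain
# proportional scaling when the floor is infeasible.
#' @noRd
scale_with_floor <- function(w, share, floor_val) {
  w <- w / sum(w) * share
  if (floor_val * length(w) >= share) return(rep(share / length(w), length(w)))
  for (i in 1:10) {
    low <- w < floor_val
    if (!any(low)) break
    w[low] <- floor_val
    w[!low] <- w[!low] * (share - floor_val * sum(low)) / sum(w[!low])
  }
  w
}

#' Generate a synthetic reactor survey
#'
#' Draws a full longitudinal dataset under a \code{\link{synthetic_spec}}:
#' system-specific log-normal core profiles rescaled to the target core share
#' (with a detectability floor), reactor-specific intermediate presence,
#' per-sample Bernoulli transients at low abundance, Dirichlet compositional
#' noise around the reactor profile with AR(1) drift between months, and
#' multinomial read counts at the target depth. Metadata rows carry plausible
#' physicochemical covariates per category (cosmetic only: they never drive
#' counts).
#'
#' @param spec a \code{synthetic_spec}.
#' @return list(table (a \code{count_table}), metadata (data.frame), truth
#'   (a \code{synthetic_truth} with per-OTU planted labels and system
#'   membership, realised per-sample core shares and the generator
#'   parameters)).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, generate_dataset_impl(spec))
}

#' @noRd
generate_dataset_impl <- function(spec) {
  layout <- make_reactor_layout(spec$n_reactors)
  layout$system <- ifelse(layout$category == "WWTP-AD", "WWTP", "AD")
  n_otus <- spec$n_otus
  otus <- sprintf("OTU_%05d", seq_len(n_otus))

  n_core <- round(spec$core_fraction * n_otus)
  n_trans <- round(spec$transient_fraction * n_otus)
  n_inter <- n_otus - n_core - n_trans
  label <- rep(c("core", "intermediate", "transient"),
               c(n_core, n_inter, n_trans))
  idx_core <- which(label == "core")
  idx_inter <- which(label == "intermediate")
  idx_trans <- which(label == "transient")

  split_systems <- function(idx, shared_fraction) {
    n <- length(idx)
    n_shared <- round(shared_fraction * n)
    n_ad <- ceiling((n - n_shared) / 2)
    sys <- rep(c("both", "AD", "WWTP"), c(n_shared, n_ad, n - n_shared - n_ad))
    stats::setNames(sys, otus[idx])
  }
  core_sys <- split_systems(idx_core, spec$shared_core_between_systems)
  inter_sys <- split_systems(idx_inter, spec$shared_core_between_systems)
  system_of <- rep("both", n_otus)
  names(system_of) <- otus
  system_of[names(core_sys)] <- core_sys
  system_of[names(inter_sys)] <- inter_sys

  inter_share <- 1 - spec$target_core_share - spec$transient_share

  # system-level core profiles
  core_weights <- list()
  for (s in c("AD", "WWTP")) {
    pool <- names(core_sys)[core_sys %in% c(s, "both")]
    if (spec$target_core_share > 0 && length(pool) == 0L) {
      stop("infeasible: no core OTUs available for system ", s, call. = FALSE)
    }
    w <- stats::rlnorm(length(pool), 0, 1)
    core_weights[[s]] <- stats::setNames(
      scale_with_floor(w, spec$target_core_share, spec$core_min_abundance), pool)
  }

  # reactor presence of intermediates: each intermediate occupies a U(0.3,0.7)
  # fraction of its system's reactors
  reactors_by_sys <- split(layout$reactor, layout$system)
  inter_presence <- list()
  for (o in names(inter_sys)) {
    systems <- if (inter_sys[[o]] == "both") c("AD", "WWTP") else inter_sys[[o]]
    pres <- character(0)
    for (s in systems) {
      rs <- reactors_by_sys[[s]]
      n_pres <- max(1L, round(stats::runif(1, 0.3, 0.7) * length(rs)))
      pres <- c(pres, sample(rs, n_pres))
    }
    inter_presence[[o]] <- pres
  }
  inters_by_reactor <- lapply(stats::setNames(layout$reactor, layout$reactor),
                              function(r) character(0))
  for (o in names(inter_presence)) {
    for (r in inter_presence[[o]]) {
      inters_by_reactor[[r]] <- c(inters_by_reactor[[r]], o)
    }
  }

  n_samples <- spec$n_reactors * spec$n_timepoints
  counts <- matrix(0L, nrow = n_samples, ncol = n_otus)
  sample_names <- character(n_samples)
  meta_rows <- vector("list", n_samples)
  delta <- if (n_trans > 0 && spec$transient_occurrence_rate > 0) {
    spec$transient_share / (spec$transient_occurrence_rate * n_trans)
  } else 0

  row_i <- 0L
  for (ri in seq_len(nrow(layout))) {
    r <- layout$reactor[ri]
    sys <- layout$system[ri]
    core_w <- core_weights[[sys]]
    inter_ids <- inters_by_reactor[[r]]
    inter_w <- if (length(inter_ids)) {
      stats::setNames(
        scale_with_floor(stats::rlnorm(length(inter_ids), 0, 1), inter_share,
                         spec$intermediate_min_abundance), inter_ids)
    } else numeric(0)
    profile <- c(core_w, inter_w)
    support <- match(names(profile), otus)
    prof_norm <- profile / sum(profile)

    turnover <- r %in% (spec$turnover_reactors %||% character(0))
    conc <- if (turnover) spec$turnover_concentration else spec$overdispersion
    a <- if (turnover) 0 else spec$temporal_autocorrelation
    alpha <- conc * prof_norm

    covars <- reactor_covariates(layout$category[ri])
    p_prev <- NULL
    for (t in seq_len(spec$n_timepoints)) {
      e <- rdirichlet1(alpha)
      p <- if (is.null(p_prev) || a == 0) e else a * p_prev + (1 - a) * e
      p_prev <- p

      pres_t <- if (n_trans > 0) {
        which(stats::runif(n_trans) < spec$transient_occurrence_rate)
      } else integer(0)
      if (length(pres_t)) {
        w_t <- delta * exp(stats::rnorm(length(pres_t), 0, 0.5) - 0.125)
        s_t <- min(sum(w_t), 0.5)
        w_t <- w_t * (s_t / sum(w_t))
      } else {
        w_t <- numeric(0)
        s_t <- 0
      }

      prob <- numeric(n_otus)
      prob[support] <- p * (1 - s_t)
      if (length(pres_t)) prob[idx_trans[pres_t]] <- w_t

      row_i <- row_i + 1L
      counts[row_i, ] <- stats::rmultinom(1L, spec$depth, prob)[, 1L]
      sid <- sprintf("%s_T%02d", r, t)
      sample_names[row_i] <- sid
      meta_rows[[row_i]] <- data.frame(
        sample_id = sid, reactor = r, unit = layout$unit[ri],
        category = layout$category[ri], reactor_role = "Fd", timepoint = t,
        pH = round(covars["pH"] + stats::rnorm(1, 0, 0.05), 2),
        temperature = round(covars["temperature"] + stats::rnorm(1, 0, 0.3), 1),
        TIC = round(covars["TIC"] + stats::rnorm(1, 0, 0.1), 2),
        NH4N = round(covars["NH4N"] + stats::rnorm(1, 0, 0.1), 2),
        TS = round(covars["TS"] + stats::rnorm(1, 0, 0.3), 2),
        VS = round(covars["VS"] + stats::rnorm(1, 0, 0.8), 1),
        total_VFA = round(stats::rlnorm(1, log(covars["total_VFA"]), 0.3)),
        stringsAsFactors = FALSE
      )
    }
  }

  dimnames(counts) <- list(sample_names, otus)
  table <- count_table(counts, domain = spec$domain, label = "synthetic")
  metadata <- do.call(rbind, meta_rows)

  # realised per-sample share of the sample's own system core pool
  sys_by_sample <- layout$system[match(metadata$reactor, layout$reactor)]
  core_share <- vapply(seq_len(n_samples), function(i) {
    pool <- names(core_sys)[core_sys %in% c(sys_by_sample[i], "both")]
    sum(counts[i, pool]) / sum(counts[i, ])
  }, numeric(1))

  truth <- structure(list(
    otus = data.frame(otu_id = otus, label = label, system = unname(system_of),
                      stringsAsFactors = FALSE),
    realised_core_share = stats::setNames(core_share, sample_names),
    params = spec
  ), class = "synthetic_truth")

  list(table = table, metadata = metadata, truth = truth)
}

# Category-typical covariate centres, spanning the reported reactor ranges
# (WWTP digesters near-neutral and low-solids, farm reactors alkaline and
# solids-rich). Cosmetic: covariates never influence the counts.
#' @noRd
reactor_covariates <- function(category) {
  base <- switch(category,
    "farm" = c(pH = 7.95, temperature = 41, TIC = 4.0, NH4N = 3.6, TS = 9.4, VS = 72.3, total_VFA = 900),
    "bio-waste" = c(pH = 7.7, temperature = 37.5, TIC = 3.5, NH4N = 2.9, TS = 8.2, VS = 67.5, total_VFA = 700),
    "MSW" = c(pH = 7.8, temperature = 39, TIC = 4.7, NH4N = 3.5, TS = 21.9, VS = 51.1, total_VFA = 1200),
    "WWTP-AD" = c(pH = 7.15, temperature = 35.5, TIC = 1.3, NH4N = 0.8, TS = 3.1, VS = 50.8, total_VFA = 300)
  )
  base + stats::rnorm(length(base), 0, c(0.03, 0.5, 0.15, 0.15, 0.4, 1.0, 50))
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d OTUs (%s); mean realised core share %.3f\n",
              nrow(x$otus),
              paste(sprintf("%s %d", names(table(x$otus$label)),
                            table(x$otus$label)), collapse = ", "),
              mean(x$realised_core_share)))
  invisible(x)
}

#' Score a partition against planted truth
#'
#' Precision and recall of the recovered core and transient sets against the
#' planted labels, evaluated within one system's scope. Planted sets are
#' restricted to OTUs belonging to that system (or both) and to the
#' partition's detected universe: an OTU that never reached a read in the
#' scope cannot be classified and is reported separately as undetected.
#'
#' @param truth a \code{synthetic_truth}.
#' @param partition an \code{otu_partition} computed over one system's samples.
#' @param system "AD" or "WWTP": the system whose samples define the
#'   partition scope.
#' @param table optional \code{count_table}; when supplied, the recovered
#'   core's mean abundance share over the scope is compared with the planted
#'   target share.
#' @return list(core, transient) each with (n_planted, n_detected,
#'   n_recovered, precision, recall), plus share = list(estimated, target,
#'   abs_error) when \code{table} is given. Precision is NA (flagged) when
#'   nothing was recovered.
#' @export
recovery_report <- function(truth, partition, system = c("AD", "WWTP"),
                            table = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(partition, "otu_partition"))
  system <- match.arg(system)
  unknown <- setdiff(partition$universe, truth$otus$otu_id)
  if (length(unknown)) {
    stop("partition OTU universe not covered by truth (",
         length(unknown), " unknown ids)", call. = FALSE)
  }
  detected <- names(partition$occurrence)
  score <- function(lab) {
    planted <- truth$otus$otu_id[truth$otus$label == lab &
                                   truth$otus$system %in% c(system, "both")]
    planted_detected <- intersect(planted, detected)
    recovered <- partition_members(partition, lab)
    tp <- length(intersect(recovered, planted_detected))
    list(
      n_planted = length(planted),
      n_detected = length(planted_detected),
      n_recovered = length(recovered),
      precision = if (length(recovered)) tp / length(recovered) else NA_real_,
      recall = if (length(planted_detected)) tp / length(planted_detected) else NA_real_
    )
  }
  out <- list(core = score("core"), transient = score("transient"))
  if (!is.null(table)) {
    est <- abundance_share(table, partition_members(partition, "core"),
                           partition$scope)$mean
    target <- truth$params$target_core_share
    out$share <- list(estimated = est, target = target,
                      abs_error = abs(est - target))
  }
  out
}
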