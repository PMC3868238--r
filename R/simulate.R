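#' Specify a synthetic drug-by-kinase activity matrix
#'
#' Describes a simulated kinase-inhibitor selectivity panel with optional
#' "spiked" drugs engineered to hit a target kinase set far more potently
#' than their background. Defaults emulate the shape of a published
#' comprehensive Kd selectivity panel (72 inhibitors by 442 kinases), with
#' background Kd drawn log-normal (location `log(1)` uM, scale 2, spanning
#' roughly four orders of magnitude, as published Kd panels do). For
#' `assay_type = "ic50"` the background percent inhibition is drawn from a
#' scaled Beta distribution.
#'
#' @param n_drugs,n_kinases Panel dimensions.
#' @param assay_type `"kd"` or `"ic50"`.
#' @param seed Integer seed; generation is reproducible per seed.
#' @param spikes List of [spike()] specifications.
#' @param kd_meanlog,kd_sdlog Log-normal parameters for background Kd (uM).
#' @param inhib_shape1,inhib_shape2 Beta shape parameters for background
#'   percent inhibition (scaled to \[0, 100\]).
#' @param missing_rate Fraction of background cells set to missing
#'   (unassayed); spiked target cells are never missing.
#' @return An object of class `fixture_spec`.
#' @seealso [generate_fixture()]
#' @export
fixture_spec <- function(n_drugs = 72L, n_kinases = 442L,
                         assay_type = c("kd", "ic50"), seed = 1L,
                         spikes = list(),
                         kd_meanlog = log(1), kd_sdlog = 2,
                         inhib_shape1 = 1.2, inhib_shape2 = 3,
                         missing_rate = 0) {
  assay_type <- match.arg(assay_type)
  n_drugs <- as.integer(n_drugs)
  n_kinases <- as.integer(n_kinases)
  stopifnot(n_drugs >= 1L, n_kinases >= 1L,
            missing_rate >= 0, missing_rate < 1)
  if (length(spikes) && !all(vapply(spikes, inherits, logical(1), "spike")))
    stop("'spikes' must be a list of spike() objects", call. = FALSE)
  targets <- unique(normalize_symbols(
    unlist(lapply(spikes, `[[`, "targets"), use.names = FALSE)))
  if (length(targets) > n_kinases)
    stop("spike target set (", length(targets),
         " kinases) larger than the kinase panel (", n_kinases, ")",
         call. = FALSE)
  if (length(spikes) > n_drugs)
    stop("more spiked drugs than drugs in the panel", call. = FALSE)
  structure(
    list(n_drugs = n_drugs, n_kinases = n_kinases, assay_type = assay_type,
         seed = as.integer(seed), spikes = spikes,
         kd_meanlog = kd_meanlog, kd_sdlog = kd_sdlog,
         inhib_shape1 = inhib_shape1, inhib_shape2 = inhib_shape2,
         missing_rate = missing_rate),
    class = "fixture_spec"
  )
}

#' Declare a spiked (engineered-specific) drug for a fixture
#'
#' The spiked drug's values on its target kinases are made better than all
#' of its background values by at least the potency-gap factor: for Kd,
#' target Kd <= min(background Kd) / gap; for percent inhibition, the
#' *residual* activity 100 - value is divided, i.e.
#' 100 - target <= (100 - max(background)) / gap.
#'
#' @param drug Drug identifier.
#' @param targets Character vector of target kinase symbols.
#' @param gap Potency-gap factor (>= 1), default 100.
#' @return An object of class `spike`.
#' @export
spike <- function(drug, targets, gap = 100) {
  stopifnot(length(drug) == 1L, length(targets) >= 1L, gap >= 1)
  structure(list(drug = as.character(drug),
                 targets = normalize_symbols(targets), gap = gap),
            class = "spike")
}

#' Generate a synthetic activity matrix
#'
#' Draws the background panel from the spec's noise model, then overwrites
#' each spiked drug's target cells so the spike invariant holds (targets
#' better than that drug's background by at least the gap factor). Two runs
#' with the same spec produce identical matrices; the caller's RNG state is
#' untouched.
#'
#' @param spec A [fixture_spec()].
#' @return An [activity_matrix()].
#' @examples
#' sp <- fixture_spec(n_drugs = 5, n_kinases = 20, seed = 7,
#'                    spikes = list(spike("specific1", "MET")))
#' am <- generate_fixture(sp)
#' rank_profiles(am)$profiles$specific1[1]  # MET at rank 1
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  target_syms <- unique(unlist(lapply(spec$spikes, `[[`, "targets"),
                               use.names = FALSE))
  n_fill <- spec$n_kinases - length(target_syms)
  kinases <- c(target_syms,
               sprintf("KIN%04d", seq_len(spec$n_kinases))[seq_len(n_fill)])
  spiked_ids <- vapply(spec$spikes, `[[`, character(1), "drug")
  if (anyDuplicated(spiked_ids))
    stop("duplicate spiked drug identifiers", call. = FALSE)
  n_fill_drugs <- spec$n_drugs - length(spiked_ids)
  drugs <- c(spiked_ids, sprintf("DRUG%03d", seq_len(spec$n_drugs))[seq_len(n_fill_drugs)])

  values <- with_local_seed(spec$seed, {
    n <- spec$n_drugs * spec$n_kinases
    v <- if (spec$assay_type == "kd") {
      stats::rlnorm(n, spec$kd_meanlog, spec$kd_sdlog)
    } else {
      100 * stats::rbeta(n, spec$inhib_shape1, spec$inhib_shape2)
    }
    v <- matrix(v, spec$n_drugs, spec$n_kinases,
                dimnames = list(drugs, kinases))
    if (spec$missing_rate > 0) {
      drop <- stats::runif(n) < spec$missing_rate
      v[drop] <- NA_real_
    }
    for (sp in spec$spikes) {
      bg <- v[sp$drug, setdiff(kinases, sp$targets)]
      bg <- bg[!is.na(bg)]
      jitter <- stats::runif(length(sp$targets), 1, 2)
      if (spec$assay_type == "kd") {
        v[sp$drug, sp$targets] <- min(bg) / (sp$gap * jitter)
      } else {
        resid <- (100 - max(bg)) / (sp$gap * jitter)
        v[sp$drug, sp$targets] <- 100 - resid
      }
    }
    v
  })
  activity_matrix(values, spec$assay_type)
}
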