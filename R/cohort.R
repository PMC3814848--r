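#' Specification of a synthetic developmental cohort
#'
#' Collects every parameter of the synthetic connectivity generator. The
#' defaults emulate the structure of a typical developmental DTI study:
#' 5 age groups of 36 subjects, 78 cortical regions in 6 planted modules,
#' network sparsity around 0.11-0.13 rising by a factor of ~1.2 from the
#' youngest to the oldest group, total fiber count rising by ~1.6, mean
#' tract FA rising with age, and a set of high-strength hub regions.
#'
#' @param n_groups Number of age groups.
#' @param n_per_group Subjects per group.
#' @param n_regions Number of cortical regions (nodes).
#' @param n_modules Number of planted modules.
#' @param p_in Probability of an intra-module candidate connection in the
#'   youngest group's anatomical template.
#' @param p_out Probability of an inter-module candidate connection.
#' @param fn_span_factor Ratio of oldest-to-youngest expected total fiber
#'   count.
#' @param sparsity_span_factor Ratio of oldest-to-youngest expected network
#'   sparsity.
#' @param fa_young,fa_old Mean tract FA at the youngest/oldest group,
#'   in (0, 1).
#' @param fn_mean Mean fiber count of a present connection in the youngest
#'   group.
#' @param fn_dispersion Negative-binomial size parameter of fiber counts
#'   (smaller = more overdispersed).
#' @param hub_fraction Fraction of nodes treated as hubs (boosted
#'   inter-module connectivity and fiber counts).
#' @param edge_consistency Probability that a template connection is
#'   present in an individual subject.
#' @param effect_map Optional list of programmed group differences; each
#'   element is `list(metric, transition, delta)` where `metric` is one of
#'   `"E_glob"`, `"E_loc"`, `"Q"`, `transition` is the index t of the
#'   adjacent-group change (groups t+1 onward are shifted) and `delta` the
#'   desired relative change of the group-mean metric.
#' @param age_ranges List of per-group `c(min, max)` age intervals in years.
#' @param sex_ratio Probability that a subject is female.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_groups = 5, n_per_group = 36, n_regions = 78,
                        n_modules = 6, p_in = 0.55, p_out = 0.035,
                        fn_span_factor = 1.6, sparsity_span_factor = 1.2,
                        fa_young = 0.40, fa_old = 0.48,
                        fn_mean = 60, fn_dispersion = 3,
                        hub_fraction = 0.10, edge_consistency = 0.97,
                        effect_map = NULL, age_ranges = NULL,
                        sex_ratio = 0.5, seed = 1L) {
  if (n_groups < 1 || n_per_group < 1)
    stop("group count and group size must be positive")
  if (n_modules > n_regions) stop("more modules than regions")
  for (p in c(p_in, p_out, edge_consistency, sex_ratio))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (fa_young <= 0 || fa_young >= 1 || fa_old <= 0 || fa_old >= 1)
    stop("FA means must lie in (0, 1)")
  if (fn_span_factor < 1 || sparsity_span_factor < 1)
    stop("span factors must be >= 1")
  if (fn_span_factor < sparsity_span_factor)
    stop("fn_span_factor must be >= sparsity_span_factor")
  if (p_in <= p_out)
    warning("p_in <= p_out: planted modules will not be recoverable")
  if (is.null(age_ranges)) {
    age_ranges <- if (n_groups == 5) {
      list(c(6.0, 9.8), c(9.9, 12.7), c(12.9, 17.6), c(17.6, 21.8),
           c(21.9, 29.7))
    } else {
      breaks <- seq(6, 30, length.out = n_groups + 1)
      lapply(seq_len(n_groups), function(g) c(breaks[g], breaks[g + 1]))
    }
  }
  if (length(age_ranges) != n_groups) stop("one age range per group required")
  structure(
    list(n_groups = n_groups, n_per_group = n_per_group,
         n_regions = n_regions, n_modules = n_modules, p_in = p_in,
         p_out = p_out, fn_span_factor = fn_span_factor,
         sparsity_span_factor = sparsity_span_factor, fa_young = fa_young,
         fa_old = fa_old, fn_mean = fn_mean, fn_dispersion = fn_dispersion,
         hub_fraction = hub_fraction, edge_consistency = edge_consistency,
         effect_map = effect_map, age_ranges = age_ranges,
         sex_ratio = sex_ratio, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Ground-truth module assignment of the generator
#'
#' Deterministically splits `n_regions` nodes into `n_modules` contiguous
#' near-equal blocks (earlier blocks take the remainder). This is the
#' planted partition against which module-recovery is scored.
#'
#' @param spec A [cohort_spec()], or the number of regions.
#' @param n_modules Number of modules (only when `spec` is a count).
#' @return An integer module-assignment vector of length `n_regions`.
#' @export
planted_partition <- function(spec, n_modules = NULL) {
  if (inherits(spec, "cohort_spec")) {
    n <- spec$n_regions
    m <- spec$n_modules
  } else {
    n <- spec
    m <- n_modules
  }
  if (m > n) stop("more modules than regions")
  sizes <- rep(n %/% m, m)
  extra <- n %% m
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  rep(seq_len(m), times = sizes)
}

# Group labels: developmental stage names for the canonical 5-group design.
group_labels <- function(n_groups) {
  if (n_groups == 5)
    return(c("early_childhood", "late_childhood", "adolescence",
             "young_adult", "adult"))
  paste0("group", seq_len(n_groups))
}

# Linear interpolation across groups: value 1 at the youngest group,
# `factor` at the oldest.
group_factor <- function(g, n_groups, factor) {
  if (n_groups == 1) return(1)
  1 + (factor - 1) * (g - 1) / (n_groups - 1)
}

# Knob response matrix of the effect-injection mechanism. Rows: relative
# change of group-mean E_glob, E_loc, Q; columns: generator knobs
# (log inter-module propensity multiplier; sub-block concentration, i.e.
# the fraction of intra-module density reallocated into cliquish ~4-node
# sub-blocks; log intra-module fiber-count multiplier). Estimated once by
# simulation at the default design (78 regions, 6 modules, p_in 0.55,
# p_out 0.035) and frozen; programmed effects are translated into knob
# settings by inverting this matrix, which compensates each knob's
# cross-talk on the other two metrics.
effect_sensitivity <- function() {
  matrix(c(
    #  dlog m_out  dlog m_in  dlog w_in
    0.25093, 0.30967, -0.09592,  # E_glob
    -0.24026, 1.47213, 0.32078,  # E_loc
    -0.40504, 0.38268, 0.47118   # Q
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("E_glob", "E_loc", "Q"),
                  c("log_m_out", "log_m_in", "log_w_in")))
}

# Translate an effect_map into per-group generator knobs. Effects are
# cumulative: a transition-t change persists in every later group.
resolve_effect_knobs <- function(effect_map, n_groups) {
  knobs <- lapply(seq_len(n_groups), function(g)
    list(m_out = 1, m_in = 1, w_in = 1))
  if (is.null(effect_map) || length(effect_map) == 0) return(knobs)
  S <- effect_sensitivity()
  S_inv <- solve(S)
  for (g in seq_len(n_groups)) {
    delta <- c(E_glob = 0, E_loc = 0, Q = 0)
    for (eff in effect_map) {
      if (!eff$metric %in% names(delta))
        stop("effect_map supports metrics E_glob, E_loc, Q")
      if (eff$transition < 1 || eff$transition >= n_groups)
        stop("effect_map transition out of range")
      if (g > eff$transition) delta[eff$metric] <- delta[eff$metric] + eff$delta
    }
    v <- S_inv %*% delta
    knobs[[g]] <- list(m_out = exp(v["log_m_out", 1]),
                       m_in = exp(v["log_m_in", 1]),
                       w_in = exp(v["log_w_in", 1]))
  }
  knobs
}


# Pairwise connection propensities of one group's anatomical template.
template_propensity <- function(spec, assign, g, knobs) {
  n <- spec$n_regions
  f_sparsity <- group_factor(g, spec$n_groups, spec$sparsity_span_factor)
  intra <- outer(assign, assign, "==")
  P <- matrix(spec$p_out * knobs$m_out, n, n)
  P[intra] <- spec$p_in * knobs$m_in
  # hub nodes: boosted inter-module connectivity
  hubs <- planted_hubs(spec, assign)
  if (length(hubs)) {
    boost <- matrix(1, n, n)
    boost[hubs, ] <- boost[hubs, ] * 1.5
    boost[, hubs] <- boost[, hubs] * 1.5
    P[!intra] <- P[!intra] * boost[!intra]
  }
  P <- P * f_sparsity
  P[P > 0.95] <- 0.95
  diag(P) <- 0
  P
}

# Deterministic hub choice: the first node of each module, cycling through
# the modules until hub_fraction * n_regions nodes are marked.
planted_hubs <- function(spec, assign) {
  n_hubs <- round(spec$hub_fraction * spec$n_regions)
  if (n_hubs == 0) return(integer(0))
  mods <- sort(unique(assign))
  picks <- integer(0)
  rank <- 1
  while (length(picks) < n_hubs) {
    for (s in mods) {
      in_s <- which(assign == s)
      if (length(in_s) >= rank) picks <- c(picks, in_s[rank])
      if (length(picks) == n_hubs) break
    }
    rank <- rank + 1
  }
  sort(picks)
}

#' Generate a synthetic multi-group cohort of subject connectivity data
#'
#' Draws a cohort with the statistical structure the downstream analysis
#' assumes. A planted-partition anatomical template is drawn per group
#' (nested across groups through shared uniforms, so older groups add
#' connections rather than reshuffling them); each subject expresses a
#' template connection with probability `edge_consistency`; present
#' connections receive negative-binomial fiber counts whose scale rises
#' across groups so that expected total fiber count grows by
#' `fn_span_factor`, truncated-normal FA around a group mean rising from
#' `fa_young` to `fa_old`, and log-normal region volumes. Hub nodes get
#' boosted inter-module connectivity and fiber counts. The optional
#' `effect_map` programs additional group differences in specific network
#' metrics (see [cohort_spec()]).
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort`: list with `subjects`
#'   (list of `subject_connectivity`), `demographics` (data frame with
#'   `subject_id`, `age`, `sex`, `group`), `planted` (module assignment),
#'   `group_order`, `templates` (per-group template adjacency) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_regions
  assign <- planted_partition(spec)
  labels <- region_labels(n)
  knobs <- resolve_effect_knobs(spec$effect_map, spec$n_groups)
  glab <- group_labels(spec$n_groups)

  # cohort-level anatomy: shared uniforms make group templates nested
  U <- matrix(stats::runif(n * n), n, n)
  U[lower.tri(U)] <- t(U)[lower.tri(U)]
  vol_base <- stats::rlnorm(n, meanlog = log(1e4), sdlog = 0.3)
  hubs <- planted_hubs(spec, assign)

  # Group templates carry only the baseline anatomy (planted modules, hubs,
  # sparsity growth); effect-map topology knobs are applied per subject
  # below, so programmed group contrasts are averaged over subjects instead
  # of riding on a single template draw.
  base_knobs <- list(m_out = 1, m_in = 1, w_in = 1)
  templates <- lapply(seq_len(spec$n_groups), function(g) {
    P <- template_propensity(spec, assign, g, base_knobs)
    tpl <- (U < P) * 1L
    diag(tpl) <- 0L
    dimnames(tpl) <- list(labels, labels)
    tpl
  })
  # per-group subject-level edge gain/drop probabilities from the knobs
  knob_deltas <- lapply(seq_len(spec$n_groups), function(g) {
    P0 <- template_propensity(spec, assign, g, base_knobs)
    P1 <- template_propensity(spec, assign, g, knobs[[g]])
    if (identical(knobs[[g]][c("m_out", "m_in")], base_knobs[c("m_out", "m_in")]))
      return(NULL)
    gain <- pmax(P1 - P0, 0) / pmax(1 - P0, 1e-12)
    drop <- pmax(P0 - P1, 0) / pmax(P0, 1e-12)
    list(gain = gain, drop = drop)
  })

  upper <- upper.tri(matrix(0, n, n))
  subjects <- list()
  demo <- list()
  sid <- 0
  for (g in seq_len(spec$n_groups)) {
    tpl <- templates[[g]]
    fa_g <- spec$fa_young +
      (spec$fa_old - spec$fa_young) * (g - 1) / max(spec$n_groups - 1, 1)
    fn_factor <- group_factor(g, spec$n_groups,
                              spec$fn_span_factor / spec$sparsity_span_factor)
    mu_g <- spec$fn_mean * fn_factor
    for (s in seq_len(spec$n_per_group)) {
      sid <- sid + 1
      keep <- matrix(0L, n, n)
      keep[upper] <- stats::rbinom(sum(upper), 1, spec$edge_consistency)
      keep <- keep + t(keep)
      pres <- tpl * keep
      kd <- knob_deltas[[g]]
      if (!is.null(kd)) {
        u_sub <- matrix(stats::runif(n * n), n, n)
        gained <- (tpl == 0) & (u_sub < kd$gain)
        dropped <- (tpl == 1) & (u_sub < kd$drop)
        pres[gained] <- 1L
        pres[dropped] <- 0L
        pres[lower.tri(pres)] <- t(pres)[lower.tri(pres)]
        diag(pres) <- 0L
      }
      idx <- which(upper & pres > 0)
      FN <- matrix(0L, n, n)
      mu_edge <- rep(mu_g, length(idx))
      # intra-module fiber-count knob of the effect-injection mechanism
      if (knobs[[g]]$w_in != 1) {
        intra_pair <- outer(assign, assign, "==")
        mu_edge[intra_pair[idx]] <- mu_edge[intra_pair[idx]] * knobs[[g]]$w_in
      }
      # hub-incident connections carry more fibers (high-strength hubs)
      if (length(hubs)) {
        hub_row <- matrix(FALSE, n, n)
        hub_row[hubs, ] <- TRUE
        hub_row[, hubs] <- TRUE
        mu_edge[hub_row[idx]] <- mu_edge[hub_row[idx]] * 1.5
      }
      FN[idx] <- 1L + stats::rnbinom(length(idx), size = spec$fn_dispersion,
                                     mu = mu_edge - 1)
      FN <- FN + t(FN)
      FA <- matrix(0, n, n)
      FA[idx] <- pmin(pmax(stats::rnorm(length(idx), fa_g, 0.06), 0.2), 0.9)
      FA <- FA + t(FA)
      volumes <- vol_base * stats::rlnorm(n, 0, 0.08)
      names(volumes) <- labels
      dimnames(FN) <- dimnames(FA) <- list(labels, labels)
      age <- stats::runif(1, spec$age_ranges[[g]][1], spec$age_ranges[[g]][2])
      sex <- if (stats::runif(1) < spec$sex_ratio) "F" else "M"
      subj <- structure(
        list(subject_id = sprintf("sub%03d", sid), age = age, sex = sex,
             group = glab[g], FN = FN, FA = FA, volumes = volumes),
        class = "subject_connectivity")
      subjects[[sid]] <- subj
      demo[[sid]] <- data.frame(subject_id = subj$subject_id, age = age,
                                sex = sex, group = glab[g])
    }
  }
  structure(
    list(subjects = subjects, demographics = do.call(rbind, demo),
         planted = assign, group_order = glab, templates = templates,
         spec = spec),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects in %d groups, %d regions, %d planted modules\n",
              length(x$subjects), x$spec$n_groups, x$spec$n_regions,
              x$spec$n_modules))
  print(table(x$demographics$group)[x$group_order])
  invisible(x)
}

#' Region label table
#'
#' `region_labels` returns plain node identifiers for an arbitrary region
#' count; for the canonical 78-region cortical parcellation (39 regions per
#' hemisphere) `cortical_region_table` returns the standard AAL cortical
#' abbreviations with hemisphere codes.
#'
#' @param n Number of regions.
#' @return `region_labels`: a character vector; `cortical_region_table`: a
#'   data frame with columns `index`, `abbreviation`, `hemisphere`.
#' @export
region_labels <- function(n) {
  if (n == 78) {
    tab <- cortical_region_table()
    return(paste0(tab$abbreviation, ".", tab$hemisphere))
  }
  sprintf("R%03d", seq_len(n))
}

#' @rdname region_labels
#' @export
cortical_region_table <- function() {
  abb <- c("REC", "OLF", "ORBsup", "ORBsupmed", "ORBmid", "ORBinf", "SFGdor",
           "MFG", "IFGoperc", "IFGtriang", "SFGmed", "SMA", "PCL", "PreCG",
           "ROL", "PoCG", "SPG", "IPL", "SMG", "ANG", "PCUN", "SOG", "MOG",
           "IOG", "CAL", "CUN", "LING", "FFG", "HES", "STG", "MTG", "ITG",
           "TPOsup", "TPOmid", "PHG", "ACG", "DCG", "PCG", "INS")
  data.frame(index = seq_len(78),
             abbreviation = rep(abb, 2),
             hemisphere = rep(c("L", "R"), each = 39))
}

#' Write a synthetic cohort to disk
#'
#' One CSV matrix per subject for FN and FA, one CSV vector of region
#' volumes, a cohort demographics CSV, a region-label TSV and a JSON
#' sidecar recording the generator settings and seed.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (subj in cohort$subjects) {
    base <- file.path(dir, subj$subject_id)
    utils::write.csv(as.data.frame(subj$FN), paste0(base, "_FN.csv"),
                     row.names = TRUE)
    utils::write.csv(as.data.frame(subj$FA), paste0(base, "_FA.csv"),
                     row.names = TRUE)
    utils::write.csv(data.frame(region = names(subj$volumes),
                                volume = subj$volumes),
                     paste0(base, "_volumes.csv"), row.names = FALSE)
  }
  utils::write.csv(cohort$demographics, file.path(dir, "demographics.csv"),
                   row.names = FALSE)
  n <- cohort$spec$n_regions
  lab_tab <- if (n == 78) cortical_region_table() else
    data.frame(index = seq_len(n), abbreviation = region_labels(n),
               hemisphere = NA_character_)
  utils::write.table(lab_tab, file.path(dir, "region_labels.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  sidecar <- cohort$spec
  class(sidecar) <- NULL
  sidecar$effect_map <- cohort$spec$effect_map
  jsonlite::write_json(sidecar, file.path(dir, "cohort_spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the cohort files.
#' @return A `synthetic_cohort`-shaped list with `subjects`, `demographics`
#'   and `group_order` (templates and planted truth are not stored on disk).
#' @export
read_cohort <- function(dir) {
  demo <- utils::read.csv(file.path(dir, "demographics.csv"),
                          stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(demo)), function(i) {
    base <- file.path(dir, demo$subject_id[i])
    FN <- as.matrix(utils::read.csv(paste0(base, "_FN.csv"), row.names = 1,
                                    check.names = FALSE))
    FA <- as.matrix(utils::read.csv(paste0(base, "_FA.csv"), row.names = 1,
                                    check.names = FALSE))
    vols <- utils::read.csv(paste0(base, "_volumes.csv"))
    volumes <- vols$volume
    names(volumes) <- vols$region
    structure(list(subject_id = demo$subject_id[i], age = demo$age[i],
                   sex = demo$sex[i], group = demo$group[i],
                   FN = FN, FA = FA, volumes = volumes),
              class = "subject_connectivity")
  })
  grp <- unique(demo$group)
  structure(list(subjects = subjects, demographics = demo,
                 group_order = grp),
            class = "synthetic_cohort")
}
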