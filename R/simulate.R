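#' Simulation configuration
#'
#' Describes a paired two-system benchmark: a planted regulatory truth (TF
#' modules with a conserved core), an in-vivo-style dose-series design, an
#' in-vitro-style control-vs-treated design, and large heterogeneous
#' compendia for network inference.
#'
#' Variance components, all in log2 units: `noise_sd` is replicate-level
#' measurement noise; `condition_sd` is per-gene condition-to-condition
#' biological variation in the compendium (expression changes not explained
#' by the planted regulators — in real compendia a single regulator explains
#' only part of a target's variance); `activity_re_sd` is the per-condition
#' random effect on a TF's latent activity in the perturbation designs.
#'
#' @param n_genes total genes (single namespace shared by both systems).
#' @param n_tfs number of transcription-factor regulators.
#' @param targets_per_tf regulon size (dedicated targets per TF).
#' @param shared_module_count how many TF modules are identical (same edges,
#'   signs and effect sizes) in both systems; remaining modules get
#'   system-specific target sets drawn on disjoint gene pools.
#' @param doses dose levels for the dose-series design (first is control).
#' @param time_points sacrifice times (h) for the dose-series design.
#' @param replicates biological replicates per dose-series condition.
#' @param vitro_replicates replicates per condition in the control-treated
#'   design.
#' @param n_compendium_conditions arrays in each network compendium.
#' @param noise_sd,condition_sd,activity_re_sd variance components (log2).
#' @param effect_mean,effect_sd,effect_min regulatory slope magnitudes:
#'   `|slope| = max(Normal(effect_mean, effect_sd), effect_min)`, random sign.
#' @param dose_coef_range TF dose-sensitivity magnitude range (uniform),
#'   random sign; the top-dose log2 shift of a target is
#'   `slope * dose_coef`.
#' @param dose_response `"linear_in_log_dose"` or `"hill"`.
#' @param baseline_log2_mean,baseline_log2_sd per-gene baseline abundance.
#' @param flag_threshold intensity below which a probe is called absent.
#' @param seed master seed; every random draw flows from it through
#'   per-(stream, gene) substreams so that adding genes or matrices does not
#'   perturb existing ones.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200L, n_tfs = 10L, targets_per_tf = 8L,
                       shared_module_count = 4L,
                       doses = c(0, 4.8, 48, 96, 192),
                       time_points = c(24, 48), replicates = 4L,
                       vitro_replicates = 3L,
                       n_compendium_conditions = 120L,
                       noise_sd = 0.3, condition_sd = 1.0,
                       activity_re_sd = 0.25,
                       effect_mean = 1.0, effect_sd = 0.2, effect_min = 0.5,
                       dose_coef_range = c(1, 2),
                       dose_response = c("linear_in_log_dose", "hill"),
                       baseline_log2_mean = 9, baseline_log2_sd = 2,
                       flag_threshold = 16, seed = 1L) {
  dose_response <- match.arg(dose_response)
  cfg <- list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
              targets_per_tf = as.integer(targets_per_tf),
              shared_module_count = as.integer(shared_module_count),
              doses = doses, time_points = time_points,
              replicates = as.integer(replicates),
              vitro_replicates = as.integer(vitro_replicates),
              n_compendium_conditions = as.integer(n_compendium_conditions),
              noise_sd = noise_sd, condition_sd = condition_sd,
              activity_re_sd = activity_re_sd,
              effect_mean = effect_mean, effect_sd = effect_sd,
              effect_min = effect_min, dose_coef_range = dose_coef_range,
              dose_response = dose_response,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              flag_threshold = flag_threshold, seed = as.integer(seed))
  if (cfg$shared_module_count > cfg$n_tfs)
    stop("shared_module_count cannot exceed n_tfs")
  n_specific <- cfg$n_tfs - cfg$shared_module_count
  need <- cfg$n_tfs + cfg$shared_module_count * cfg$targets_per_tf +
    2L * n_specific * cfg$targets_per_tf
  if (need > cfg$n_genes)
    stop(sprintf("n_genes = %d too small for the requested modules (need >= %d)",
                 cfg$n_genes, need))
  if (any(c(cfg$n_tfs, cfg$targets_per_tf, cfg$replicates,
            cfg$n_compendium_conditions) < 1L))
    stop("all counts must be >= 1")
  if (cfg$noise_sd < 0 || cfg$condition_sd < 0)
    stop("noise_sd and condition_sd must be >= 0")
  structure(cfg, class = "sim_config")
}

# deterministic substream seed: polynomial hash of (seed, ids...) mod 2^31-1,
# with a final multiplicative step so consecutive ids map to distant seeds
substream_seed <- function(seed, ...) {
  h <- as.double(seed) %% 2147483647
  for (id in c(...)) h <- (h * 48271 + as.double(id) + 1) %% 2147483647
  h <- (h * 48271) %% 2147483647
  as.integer(max(h, 1))
}

sim_gene_ids <- function(cfg) {
  c(sprintf("TF%02d", seq_len(cfg$n_tfs)),
    sprintf("G%04d", (cfg$n_tfs + 1L):cfg$n_genes))
}

#' Generate paired planted truth networks
#'
#' Two regulator-to-target truth networks over one gene namespace. The first
#' `shared_module_count` TF modules are edge-identical in both systems (same
#' targets, signs, effect sizes and dose sensitivities); the remaining
#' modules draw their target sets on disjoint gene pools, so the edge
#' intersection of the two truths is exactly the shared modules.
#'
#' @param cfg a [sim_config()].
#' @return A list with `a` and `b`, each a `truth_network`: a data frame
#'   (`regulator`, `target`, `effect`, `module`, `label`) with attributes
#'   `regulators`, `dose_coef` (named per-TF dose sensitivity), `gene_ids`
#'   and `config`.
#' @export
generate_truth_networks <- function(cfg) {
  ids <- sim_gene_ids(cfg)
  tfs <- ids[seq_len(cfg$n_tfs)]
  pool <- ids[-seq_len(cfg$n_tfs)]
  n_sh <- cfg$shared_module_count
  n_sp <- cfg$n_tfs - n_sh
  tpt <- cfg$targets_per_tf
  set.seed(substream_seed(cfg$seed, 1))
  shared_tgt <- if (n_sh > 0) sample(pool, n_sh * tpt) else character()
  rest <- setdiff(pool, shared_tgt)
  spec_a <- if (n_sp > 0) sample(rest, n_sp * tpt) else character()
  spec_b <- if (n_sp > 0) sample(setdiff(rest, spec_a), n_sp * tpt) else character()
  draw_effects <- function(n)
    sample(c(-1, 1), n, replace = TRUE) *
      pmax(stats::rnorm(n, cfg$effect_mean, cfg$effect_sd), cfg$effect_min)
  shared_eff <- draw_effects(n_sh * tpt)
  eff_a <- draw_effects(n_sp * tpt)
  eff_b <- draw_effects(n_sp * tpt)
  draw_dose_coef <- function(n)
    sample(c(-1, 1), n, replace = TRUE) *
      stats::runif(n, cfg$dose_coef_range[1L], cfg$dose_coef_range[2L])
  dose_sh <- draw_dose_coef(n_sh)
  dose_a <- c(dose_sh, draw_dose_coef(n_sp))
  dose_b <- c(dose_sh, draw_dose_coef(n_sp))
  names(dose_a) <- names(dose_b) <- tfs
  mk <- function(spec_tgt, eff, dose_coef, label_specific) {
    edges <- data.frame(
      regulator = c(rep(tfs[seq_len(n_sh)], each = tpt),
                    rep(tfs[n_sh + seq_len(n_sp)], each = tpt)),
      target = c(shared_tgt, spec_tgt),
      effect = c(shared_eff, eff),
      stringsAsFactors = FALSE)
    edges$module <- edges$regulator
    edges$label <- c(rep("shared", n_sh * tpt),
                     rep(label_specific, n_sp * tpt))
    structure(edges, class = c("truth_network", "data.frame"),
              regulators = tfs, dose_coef = dose_coef,
              gene_ids = ids, config = cfg)
  }
  list(a = mk(spec_a, eff_a, dose_a, "system_a_only"),
       b = mk(spec_b, eff_b, dose_b, "system_b_only"))
}

#' @export
print.truth_network <- function(x, ...) {
  cat(sprintf("truth_network: %d regulators, %d edges (%d shared)\n",
              length(attr(x, "regulators")), nrow(x),
              sum(x$label == "shared")))
  invisible(x)
}

dose_response_f <- function(dose, doses, shape) {
  top <- max(doses)
  if (shape == "hill") {
    pos <- doses[doses > 0]
    K <- exp(mean(log(pos)))
    (dose^2 / (dose^2 + K^2)) / (top^2 / (top^2 + K^2))
  } else {
    log2(1 + dose) / log2(1 + top)
  }
}

#' Simulate expression data from a planted truth
#'
#' Linear-Gaussian regulation on log2 scale: a TF's latent activity is its
#' own condition-level expression; each target's log2 deviation is the sum
#' of signed slope times regulator activity plus Gaussian noise; unconnected
#' genes are independent noise. Values are returned on intensity scale
#' (`2^(baseline + deviation)`) with present/absent flags, so the full
#' normalization chain applies.
#'
#' Three designs are supported: `"compendium"` (heterogeneous single-array
#' conditions with TF activities drawn independently per condition, for
#' network inference), `"dose_series"` (doses x time points x replicates; TF
#' activity = dose sensitivity x dose-response + condition random effect),
#' and `"control_treated"` (control vs full-response treated, for the
#' two-group t-test design).
#'
#' @param truth a `truth_network` from [generate_truth_networks()], or
#'   `NULL` for a pure-noise (global null) matrix.
#' @param cfg a [sim_config()]; when `truth` is given, defaults to its
#'   stored config.
#' @param design one of `"compendium"`, `"dose_series"`,
#'   `"control_treated"`.
#' @param stream integer stream label separating the random substreams of
#'   different matrices drawn from one seed (e.g. the two systems'
#'   compendia).
#' @param log2_output return log2 values without baseline instead of
#'   intensities (convenient for direct network inference).
#' @return A list: `matrix` (an `ExpressionMatrix`), `design` (design data
#'   frame), `truth_de_shift` (named per-gene expected top-dose log2 shift;
#'   dose designs only).
#' @export
simulate_expression <- function(truth, cfg = NULL,
                                design = c("compendium", "dose_series",
                                           "control_treated"),
                                stream = 1L, log2_output = FALSE) {
  design <- match.arg(design)
  if (is.null(cfg)) {
    if (is.null(truth)) stop("cfg is required when truth is NULL")
    cfg <- attr(truth, "config")
  }
  ids <- if (is.null(truth)) sim_gene_ids(cfg) else attr(truth, "gene_ids")
  G <- length(ids)
  tfs <- ids[seq_len(cfg$n_tfs)]
  sys_label <- switch(design, dose_series = "in_vivo",
                      control_treated = "in_vitro", "compendium")

  if (design == "compendium") {
    n_cond <- cfg$n_compendium_conditions
    samples <- sprintf("%s_s%03d", sys_label, seq_len(n_cond))
    des <- data.frame(sample_id = samples, system = sys_label,
                      compound = sprintf("C%03d", seq_len(n_cond)),
                      dose = 1, time_h = 24, replicate = 1L,
                      is_control = FALSE, stringsAsFactors = FALSE)
    act <- matrix(0, cfg$n_tfs, n_cond, dimnames = list(tfs, NULL))
    for (t in seq_len(cfg$n_tfs)) {
      set.seed(substream_seed(cfg$seed, stream, 10000 + t))
      act[t, ] <- stats::rnorm(n_cond)
    }
    cond_sd <- cfg$condition_sd
    n_per_sample <- 1L
  } else if (design == "dose_series") {
    grid <- expand.grid(replicate = seq_len(cfg$replicates),
                        dose = cfg$doses, time_h = cfg$time_points)
    samples <- sprintf("%s_d%g_t%g_r%d", sys_label, grid$dose, grid$time_h,
                       grid$replicate)
    des <- data.frame(sample_id = samples, system = sys_label,
                      compound = "TNT", dose = grid$dose,
                      time_h = grid$time_h, replicate = grid$replicate,
                      is_control = grid$dose == 0, stringsAsFactors = FALSE)
    cond <- paste(grid$dose, grid$time_h)
    cond_levels <- unique(cond)
    f <- dose_response_f(grid$dose, cfg$doses, cfg$dose_response)
    act <- matrix(0, cfg$n_tfs, nrow(grid), dimnames = list(tfs, NULL))
    dose_coef <- if (is.null(truth)) stats::setNames(numeric(cfg$n_tfs), tfs)
                 else attr(truth, "dose_coef")
    for (t in seq_len(cfg$n_tfs)) {
      set.seed(substream_seed(cfg$seed, stream, 20000 + t))
      re <- stats::rnorm(length(cond_levels), 0, cfg$activity_re_sd)
      act[t, ] <- dose_coef[t] * f + re[match(cond, cond_levels)]
    }
    cond_sd <- 0
  } else {
    grid <- expand.grid(replicate = seq_len(cfg$vitro_replicates),
                        treated = c(FALSE, TRUE))
    samples <- sprintf("%s_%s_r%d", sys_label,
                       ifelse(grid$treated, "trt", "ctl"), grid$replicate)
    des <- data.frame(sample_id = samples, system = sys_label,
                      compound = "TNT",
                      dose = ifelse(grid$treated, 10, 0), time_h = 24,
                      replicate = grid$replicate,
                      is_control = !grid$treated, stringsAsFactors = FALSE)
    dose_coef <- if (is.null(truth)) stats::setNames(numeric(cfg$n_tfs), tfs)
                 else attr(truth, "dose_coef")
    act <- matrix(0, cfg$n_tfs, nrow(grid), dimnames = list(tfs, NULL))
    for (t in seq_len(cfg$n_tfs)) {
      set.seed(substream_seed(cfg$seed, stream, 30000 + t))
      re <- stats::rnorm(2, 0, cfg$activity_re_sd)
      act[t, ] <- dose_coef[t] * as.numeric(grid$treated) +
        re[grid$treated + 1L]
    }
    cond_sd <- 0
  }

  n_samp <- ncol(act)
  X <- matrix(0, G, n_samp, dimnames = list(ids, samples))
  X[tfs, ] <- act
  if (!is.null(truth)) {
    for (e in seq_len(nrow(truth)))
      X[truth$target[e], ] <- X[truth$target[e], ] +
        truth$effect[e] * act[truth$regulator[e], ]
  }
  # per-gene noise substreams: condition-level variation + replicate noise.
  # A TF's condition-level variation IS its activity (already drawn), so TFs
  # receive measurement noise only.
  for (g in seq_len(G)) {
    set.seed(substream_seed(cfg$seed, stream, 100 + g))
    noise <- stats::rnorm(n_samp, 0, cfg$noise_sd)
    if (cond_sd > 0 && !(ids[g] %in% tfs))
      noise <- noise + stats::rnorm(n_samp, 0, cond_sd)
    X[g, ] <- X[g, ] + noise
  }
  # expected top-dose log2 shift per gene (dose designs)
  truth_de_shift <- stats::setNames(numeric(G), ids)
  if (!is.null(truth) && design != "compendium") {
    dc <- attr(truth, "dose_coef")
    truth_de_shift[tfs] <- abs(dc)
    for (e in seq_len(nrow(truth)))
      truth_de_shift[truth$target[e]] <- truth_de_shift[truth$target[e]] +
        truth$effect[e] * dc[truth$regulator[e]]
    truth_de_shift[setdiff(ids, tfs)] <-
      abs(truth_de_shift[setdiff(ids, tfs)])
  }
  if (log2_output) {
    em <- expression_matrix(X, scale = "log2")
  } else {
    set.seed(substream_seed(cfg$seed, 0, 99))
    baseline <- stats::rnorm(G, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
    intens <- 2^(baseline + X)
    flags <- intens >= cfg$flag_threshold
    em <- expression_matrix(intens, scale = "intensity", flags = flags)
  }
  list(matrix = em, design = des, truth_de_shift = truth_de_shift)
}

#' Write a complete fixture bundle
#'
#' Generates the paired truths plus four datasets (system A dose series,
#' system B control-vs-treated, and both systems' network compendia) and
#' writes every pipeline input: expression TSVs with flag files, design
#' TSVs, truth edge lists and the TF list. Deterministic: two bundles from
#' the same config are file-identical.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_fixture_bundle <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truths <- generate_truth_networks(cfg)
  p <- function(...) file.path(dir, paste0(...))
  out <- c()
  datasets <- list(
    vivo = simulate_expression(truths$a, cfg, "dose_series", stream = 21),
    vitro = simulate_expression(truths$b, cfg, "control_treated", stream = 31),
    compendium_a = simulate_expression(truths$a, cfg, "compendium", stream = 11),
    compendium_b = simulate_expression(truths$b, cfg, "compendium", stream = 12))
  for (nm in names(datasets)) {
    d <- datasets[[nm]]
    write_expression_matrix(d$matrix, p(nm, "_matrix.tsv"),
                            flag_path = p(nm, "_flags.tsv"))
    write_study_design(d$design, p(nm, "_design.tsv"))
    out <- c(out, p(nm, "_matrix.tsv"), p(nm, "_flags.tsv"),
             p(nm, "_design.tsv"))
  }
  for (s in c("a", "b")) {
    utils::write.table(as.data.frame(truths[[s]]), p("truth_", s, ".tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out <- c(out, p("truth_", s, ".tsv"))
  }
  writeLines(attr(truths$a, "regulators"), p("tf_list.txt"))
  out <- c(out, p("tf_list.txt"))
  invisible(out)
}
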