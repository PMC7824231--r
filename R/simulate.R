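#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions the pipeline is designed for: a
#' birth cohort of ~201 children with feeding-mode prevalences of 22.9%
#' exclusive breastfeeding (EBF), 8.9% exclusive formula feeding (EFF) and
#' 68.2% mixed feeding, paired methylation at birth and age 10, a small
#' downward epigenome-wide shift of the age-10 values in the EFF group
#' (-0.03 M-units) and per-CpG feeding effects of 0.4 M-units on the
#' birth-to-10y change at a small CpG subset per mode.
#'
#' @param n_subjects Number of subjects (default 201).
#' @param n_cpgs Number of CpGs (default 10000).
#' @param n_effect_cpgs_per_mode CpGs per feeding mode carrying a true
#'   effect on the birth-to-10y change (default 30; the three sets are
#'   disjoint).
#' @param effect_size_m Effect size in M-value units added at age 10 to
#'   that mode's subjects at its effect CpGs (default 0.4).
#' @param global_shift_eff Mean M-value shift applied to all age-10 values
#'   of EFF subjects (default -0.03).
#' @param feeding_probs Named probabilities for EBF, EFF, Mixed; must sum
#'   to 1.
#' @param cell_type_count Number of leukocyte types (default 6:
#'   CD8T, CD4T, NK, Bcell, Mono, Gran).
#' @param season_levels Season labels; winter is the reference.
#' @param noise_sd_m Residual noise SD on the M scale per timepoint
#'   (default 0.5).
#' @param baseline_beta_params Shape pair `(a, b)`; baseline CpG means are
#'   drawn from an equal mixture of Beta(a, b) (hypomethylated mode) and
#'   Beta(b, a) (hypermethylated mode), default `c(2, 8)`.
#' @param baseline_subject_sd SD of the subject-by-CpG baseline deviation
#'   carried across both ages (default 0.3 M-units).
#' @param cell_coefs M-value effect per unit cell proportion, length
#'   `cell_type_count` (granulocyte coefficient 0 as reference).
#' @param season_coefs M-value effects of spring/summer/fall vs winter.
#' @param age_effect_m Common mean M-value change from birth to age 10
#'   (default 0.1).
#' @param seed Integer RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 201L,
                       n_cpgs = 10000L,
                       n_effect_cpgs_per_mode = 30L,
                       effect_size_m = 0.4,
                       global_shift_eff = -0.03,
                       feeding_probs = c(EBF = 0.229, EFF = 0.089, Mixed = 0.682),
                       cell_type_count = 6L,
                       season_levels = SEASON_LEVELS,
                       noise_sd_m = 0.5,
                       baseline_beta_params = c(2, 8),
                       baseline_subject_sd = 0.3,
                       cell_coefs = c(2, -1.5, 1, -1, 0.5, 0),
                       season_coefs = c(0.1, -0.1, 0.05),
                       age_effect_m = 0.1,
                       seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_cpgs = as.integer(n_cpgs),
              n_effect_cpgs_per_mode = as.integer(n_effect_cpgs_per_mode),
              effect_size_m = effect_size_m,
              global_shift_eff = global_shift_eff,
              feeding_probs = feeding_probs,
              cell_type_count = as.integer(cell_type_count),
              season_levels = season_levels,
              noise_sd_m = noise_sd_m,
              baseline_beta_params = baseline_beta_params,
              baseline_subject_sd = baseline_subject_sd,
              cell_coefs = cell_coefs,
              season_coefs = season_coefs,
              age_effect_m = age_effect_m,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (abs(sum(cfg$feeding_probs) - 1) > 1e-12) {
    stop("feeding_probs must sum to 1", call. = FALSE)
  }
  if (length(cfg$feeding_probs) != 3) {
    stop("feeding_probs must have three entries (EBF, EFF, Mixed)",
         call. = FALSE)
  }
  if (any(c(cfg$n_subjects, cfg$n_cpgs) <= 0)) {
    stop("n_subjects and n_cpgs must be positive", call. = FALSE)
  }
  if (cfg$n_effect_cpgs_per_mode < 0 ||
      3L * cfg$n_effect_cpgs_per_mode > cfg$n_cpgs) {
    stop("n_effect_cpgs_per_mode must be non-negative and the three ",
         "disjoint effect sets must fit inside n_cpgs", call. = FALSE)
  }
  if (length(cfg$cell_coefs) != cfg$cell_type_count) {
    stop("cell_coefs must have length cell_type_count", call. = FALSE)
  }
  if (length(cfg$season_coefs) != length(cfg$season_levels) - 1L) {
    stop("season_coefs must have one entry per non-reference season",
         call. = FALSE)
  }
  if (cfg$noise_sd_m < 0 || cfg$baseline_subject_sd < 0) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  invisible(cfg)
}

#' Classify infant feeding mode from feeding durations
#'
#' Uses the 13-week (three-month) cutoff. A child is EBF when only
#' breastmilk was given for at least 13 weeks before formula or solids
#' were introduced; EFF when only formula (no breastfeeding) was given for
#' at least 13 weeks before solids; otherwise Mixed (a mixture of feeding
#' sources occurred before 13 weeks). Exactly 13 weeks qualifies as
#' "at least 13 weeks". Missing introduction ages mean "never introduced".
#'
#' @param bf_weeks Weeks of breastfeeding (0 = never breastfed).
#' @param formula_week Week at which formula was introduced (`NA` = never).
#' @param solids_week Week at which solids were introduced (`NA` = never).
#' @return Character vector of `"EBF"`, `"EFF"` or `"Mixed"`.
#' @examples
#' derive_feeding_mode(16, 16, 17)  # EBF
#' derive_feeding_mode(0, 0, 20)    # EFF
#' derive_feeding_mode(10, 6, 18)   # Mixed
#' @export
derive_feeding_mode <- function(bf_weeks, formula_week, solids_week) {
  n <- max(length(bf_weeks), length(formula_week), length(solids_week))
  bf <- rep_len(bf_weeks, n)
  fo <- rep_len(formula_week, n)
  so <- rep_len(solids_week, n)
  if (any(is.na(bf) & is.na(fo) & is.na(so))) {
    stop("at least one feeding source must be present for every subject",
         call. = FALSE)
  }
  if (any(c(bf, fo, so) < 0, na.rm = TRUE)) {
    stop("feeding durations must be non-negative", call. = FALSE)
  }
  bf[is.na(bf)] <- 0
  fo[is.na(fo)] <- Inf
  so[is.na(so)] <- Inf
  first_other <- pmin(fo, so)
  mode <- rep("Mixed", n)
  mode[bf >= 13 & first_other >= 13] <- "EBF"
  mode[bf == 0 & so >= 13] <- "EFF"
  mode
}

# Dirichlet draws via normalized gammas; rows sum to 1 exactly up to
# floating point.
rdirichlet_mat <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

# Feeding durations consistent with an assigned mode, so that
# derive_feeding_mode() round-trips on generated sheets.
sample_feeding_durations <- function(modes) {
  n <- length(modes)
  bf <- fo <- so <- numeric(n)
  ebf <- modes == "EBF"
  eff <- modes == "EFF"
  mix <- modes == "Mixed"
  # EBF: breastfed beyond 13 weeks, formula/solids only afterwards
  bf[ebf] <- 13 + rpois(sum(ebf), 5)
  fo[ebf] <- bf[ebf] + rpois(sum(ebf), 2)
  so[ebf] <- bf[ebf] + 1 + rpois(sum(ebf), 3)
  # EFF: formula from birth, solids at/after 13 weeks
  bf[eff] <- 0
  fo[eff] <- 0
  so[eff] <- 13 + rpois(sum(eff), 3)
  # Mixed: another feeding source before 13 weeks
  n_mix <- sum(mix)
  bf[mix] <- rpois(n_mix, 8)
  fo[mix] <- sample(0:12, n_mix, replace = TRUE)
  so[mix] <- 13 + rpois(n_mix, 3)
  so[mix & bf == 0] <- sample(4:12, sum(mix & bf == 0), replace = TRUE)
  data.frame(bf_weeks = bf, formula_week = fo, solids_week = so)
}

# Age-specific Dirichlet concentrations for the 6 blood cell types;
# granulocytes dominate whole blood, lymphocyte fractions are a little
# higher in childhood than at birth.
CELL_ALPHA <- list(
  birth = c(CD8T = 5, CD4T = 10, NK = 3, Bcell = 5, Mono = 5, Gran = 32),
  age10 = c(CD8T = 6, CD4T = 12, NK = 3, Bcell = 6, Mono = 4, Gran = 29)
)

#' Simulate a paired-timepoint methylation cohort with known truth
#'
#' Generates beta-value matrices at birth and age 10, a sample sheet and a
#' ground-truth record. The generative model works on the M scale:
#' \deqn{M_{ij}(t) = \mu_i + b_{ij} + \gamma' cells_{j}(t) + season_{j}(t)
#'   + age(t) + effect_{ij}(t) + shift_j(t) + \epsilon_{ijt}}
#' where \eqn{\mu_i} is a bimodal per-CpG baseline, \eqn{b_{ij}} a
#' subject-level baseline carried across both ages, feeding effects apply
#' only at age 10 at that mode's effect CpGs, and the global EFF shift
#' applies to all age-10 values of EFF subjects. Betas are the inverse
#' logit2 of M, hence strictly inside (0, 1). The same seed reproduces the
#' output bit for bit.
#'
#' @param config A [sim_config()].
#' @return List with `birth` and `age10` ([meth_matrix()], beta scale),
#'   `sheet` (sample sheet) and `truth` (list: `effect_cpg_ids` per mode,
#'   `effect_size_m`, `global_shift_eff`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_subjects
  p <- config$n_cpgs
  subjects <- sprintf("S%04d", seq_len(n))
  cpgs <- sprintf("cg%08d", seq_len(p))

  modes <- sample(FEEDING_MODES, n, replace = TRUE,
                  prob = config$feeding_probs)
  durations <- sample_feeding_durations(modes)

  if (config$cell_type_count == 6L) {
    cell_names <- CELL_TYPES
    alpha <- CELL_ALPHA
  } else {
    cell_names <- paste0("cell", seq_len(config$cell_type_count))
    alpha <- list(birth = rep(5, config$cell_type_count),
                  age10 = rep(5, config$cell_type_count))
  }
  cells_birth <- rdirichlet_mat(n, alpha$birth)
  cells_age10 <- rdirichlet_mat(n, alpha$age10)
  colnames(cells_birth) <- paste0(cell_names, "_birth")
  colnames(cells_age10) <- paste0(cell_names, "_age10")

  season_birth <- sample(config$season_levels, n, replace = TRUE)
  season_age10 <- sample(config$season_levels, n, replace = TRUE)

  sheet <- data.frame(
    subject_id = subjects,
    feeding_mode = modes,
    durations,
    cells_birth, cells_age10,
    season_birth = season_birth,
    season_age10 = season_age10,
    sex = sample(c("male", "female"), n, TRUE, prob = c(0.577, 0.423)),
    maternal_smoking = sample(c("yes", "no"), n, TRUE, prob = c(0.195, 0.805)),
    maternal_age = rnorm(n, 29.6, 4.5),
    birthweight = rnorm(n, 3.3, 0.6),
    birth_order = sample(c("1", "2", "3+"), n, TRUE,
                         prob = c(0.426, 0.319, 0.255)),
    ses = sample(c("high", "medium", "low"), n, TRUE,
                 prob = c(0.105, 0.771, 0.124)),
    caesarean = sample(c("yes", "no"), n, TRUE, prob = c(0.114, 0.886)),
    maternal_asthma = sample(c("yes", "no"), n, TRUE, prob = c(0.125, 0.875)),
    stringsAsFactors = FALSE
  )

  # Disjoint effect CpG sets per feeding mode
  n_eff <- config$n_effect_cpgs_per_mode
  shuffled <- sample(cpgs)
  effect_ids <- list(
    EBF = sort(shuffled[seq_len(n_eff)]),
    EFF = sort(shuffled[n_eff + seq_len(n_eff)]),
    Mixed = sort(shuffled[2L * n_eff + seq_len(n_eff)])
  )
  if (n_eff == 0L) effect_ids <- lapply(effect_ids, function(x) character(0))

  # Baseline: bimodal per-CpG mean on the beta scale -> M, plus a
  # subject-by-CpG deviation shared by both ages.
  a <- config$baseline_beta_params[1]
  b <- config$baseline_beta_params[2]
  hyper <- runif(p) < 0.5
  mu_beta <- ifelse(hyper, rbeta(p, b, a), rbeta(p, a, b))
  mu_m <- beta_to_m(pmin(pmax(mu_beta, 0.01), 0.99))
  baseline <- mu_m + matrix(rnorm(p * n, 0, config$baseline_subject_sd), p, n)

  season_effect <- function(season) {
    eff <- c(0, config$season_coefs)[match(season, config$season_levels)]
    matrix(eff, nrow = p, ncol = n, byrow = TRUE)
  }
  cell_effect <- function(cells) {
    matrix(as.vector(cells %*% config$cell_coefs), p, n, byrow = TRUE)
  }

  noise <- function() {
    if (config$noise_sd_m == 0) matrix(0, p, n)
    else matrix(rnorm(p * n, 0, config$noise_sd_m), p, n)
  }

  m_birth <- baseline + cell_effect(cells_birth) +
    season_effect(season_birth) + noise()

  m_age10 <- baseline + cell_effect(cells_age10) +
    season_effect(season_age10) + config$age_effect_m + noise()
  for (mode in FEEDING_MODES) {
    rows <- match(effect_ids[[mode]], cpgs)
    cols <- which(modes == mode)
    if (length(rows) && length(cols)) {
      m_age10[rows, cols] <- m_age10[rows, cols] + config$effect_size_m
    }
  }
  m_age10[, modes == "EFF"] <- m_age10[, modes == "EFF"] +
    config$global_shift_eff

  dimnames(m_birth) <- dimnames(m_age10) <- list(cpgs, subjects)
  list(
    birth = meth_matrix(m_to_beta(m_birth), "beta"),
    age10 = meth_matrix(m_to_beta(m_age10), "beta"),
    sheet = validate_sample_sheet(sheet),
    truth = list(effect_cpg_ids = effect_ids,
                 effect_size_m = config$effect_size_m,
                 global_shift_eff = config$global_shift_eff,
                 modes = setNames(modes, subjects))
  )
}

#' Write a simulated cohort to disk
#'
#' Beta matrices as TSV, sample sheet and truth as CSV.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_meth_matrix(cohort$birth, file.path(dir, "beta_birth.tsv"))
  write_meth_matrix(cohort$age10, file.path(dir, "beta_age10.tsv"))
  write_sample_sheet(cohort$sheet, file.path(dir, "sample_sheet.csv"))
  truth <- do.call(rbind, lapply(FEEDING_MODES, function(m) {
    ids <- cohort$truth$effect_cpg_ids[[m]]
    if (!length(ids)) return(NULL)
    data.frame(mode = m, cpg_id = ids,
               effect_size_m = cohort$truth$effect_size_m)
  }))
  if (is.null(truth)) truth <- data.frame(mode = character(0),
                                          cpg_id = character(0),
                                          effect_size_m = numeric(0))
  data.table::fwrite(truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
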