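#' Configuration for the single-cell simulator
#'
#' Defaults emulate the structure of a multi-patient PDAC single-cell
#' study at desk scale: five patients, five cell types (two tumor types,
#' ETC and EMT, whose expression carries patient-specific shifts so tumor
#' cells segregate by patient; three stromal/immune types that mix across
#' patients), ten planted marker genes per type at an 8-fold mean
#' elevation, negative-binomial counts and a log-normal per-cell library
#' size factor.
#'
#' @param n_patients Number of patients.
#' @param cells_per_patient Cells simulated per patient.
#' @param cell_types Character vector of cell-type names.
#' @param cell_type_props Either a probability vector over `cell_types`
#'   (recycled for every patient) or an `n_patients x n_types` matrix of
#'   per-patient proportions; rows must sum to 1.
#' @param tumor_types Cell types that receive patient-specific expression
#'   shifts (the patient-segregated compartment).
#' @param n_genes Total genes in the simulated universe.
#' @param n_markers_per_type Planted markers per cell type.
#' @param marker_fold Mean multiplier (> 1) for a type's markers in cells
#'   of that type.
#' @param patient_shift_sd SD of the per-(patient, gene) log-scale mean
#'   shift applied only to tumor-type cells.
#' @param nb_dispersion Negative-binomial size parameter theta
#'   (variance = mu + mu^2 / theta).
#' @param base_mean Baseline per-gene mean count.
#' @param libsize_lognormal_sd SD of the per-cell log-normal library-size
#'   factor.
#' @param seed Integer seed; simulation is deterministic given the seed.
#' @return A validated `ScSimConfig` list.
#' @export
sc_sim_config <- function(n_patients = 5,
                          cells_per_patient = 500,
                          cell_types = c("ETC", "EMT", "CAF", "TIL", "TAM"),
                          cell_type_props = rep(1 / length(cell_types),
                                                length(cell_types)),
                          tumor_types = c("ETC", "EMT"),
                          n_genes = 500,
                          n_markers_per_type = 10,
                          marker_fold = 8,
                          patient_shift_sd = 0.5,
                          nb_dispersion = 2,
                          base_mean = 3,
                          libsize_lognormal_sd = 0.3,
                          seed = 1L) {
  n_types <- length(cell_types)
  if (is.matrix(cell_type_props)) {
    props <- cell_type_props
  } else {
    props <- matrix(cell_type_props, nrow = n_patients, ncol = n_types,
                    byrow = TRUE)
  }
  if (ncol(props) != n_types || nrow(props) != n_patients) {
    stop("cell_type_props must be a vector over cell types or an ",
         "n_patients x n_types matrix")
  }
  if (any(props < 0) || any(rowSums(props) == 0)) {
    stop("cell_type_props rows must be non-negative with positive sum")
  }
  if (any(abs(rowSums(props) - 1) > 1e-9)) {
    stop("each cell_type_props row must sum to 1")
  }
  for (v in c(n_patients, cells_per_patient, n_genes, n_markers_per_type)) {
    if (v < 1) stop("sizes must be positive")
  }
  if (marker_fold < 1) stop("marker_fold must be >= 1")
  if (patient_shift_sd < 0 || libsize_lognormal_sd < 0) {
    stop("standard deviations must be non-negative")
  }
  if (nb_dispersion <= 0 || base_mean <= 0) {
    stop("nb_dispersion and base_mean must be positive")
  }
  if (n_markers_per_type * n_types > n_genes) {
    stop("not enough genes to plant the requested markers")
  }
  structure(list(
    n_patients = n_patients, cells_per_patient = cells_per_patient,
    cell_types = cell_types, cell_type_props = props,
    tumor_types = tumor_types, n_genes = n_genes,
    n_markers_per_type = n_markers_per_type, marker_fold = marker_fold,
    patient_shift_sd = patient_shift_sd, nb_dispersion = nb_dispersion,
    base_mean = base_mean, libsize_lognormal_sd = libsize_lognormal_sd,
    seed = as.integer(seed)), class = "ScSimConfig")
}

#' Simulate a multi-patient single-cell count matrix with planted truth
#'
#' Counts are drawn gene-wise from a negative binomial with mean
#' `base_mean * marker_fold^(gene is a marker of the cell's type) *
#' exp(patient shift, tumor types only) * library-size factor` and size
#' `nb_dispersion`. The per-(patient, gene) shifts are what make tumor
#' cells cluster by patient while stromal cells mix.
#'
#' @param cfg An `ScSimConfig` from [sc_sim_config()].
#' @return List with `matrix` (a `CountMatrix`), `truth` (per-cell type
#'   label, parallel to the cells) and `marker_panel` (named list of the
#'   planted marker genes per type).
#' @export
simulate_sc <- function(cfg) {
  stopifnot(inherits(cfg, "ScSimConfig"))
  set.seed(cfg$seed)
  n_types <- length(cfg$cell_types)
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  marker_panel <- lapply(seq_len(n_types), function(t) {
    genes[((t - 1) * cfg$n_markers_per_type + 1):(t * cfg$n_markers_per_type)]
  })
  names(marker_panel) <- cfg$cell_types

  # per-type baseline mean vector (marker elevation applied)
  type_mu <- matrix(cfg$base_mean, nrow = cfg$n_genes, ncol = n_types,
                    dimnames = list(genes, cfg$cell_types))
  for (t in seq_len(n_types)) {
    type_mu[marker_panel[[t]], t] <- cfg$base_mean * cfg$marker_fold
  }

  patients <- sprintf("P%02d", seq_len(cfg$n_patients))
  # per-(patient, gene) tumor shifts, shared by all tumor types of a patient
  shifts <- matrix(stats::rnorm(cfg$n_patients * cfg$n_genes,
                                sd = cfg$patient_shift_sd),
                   nrow = cfg$n_genes, ncol = cfg$n_patients,
                   dimnames = list(genes, patients))

  n_cells <- cfg$n_patients * cfg$cells_per_patient
  cell_patient <- rep(patients, each = cfg$cells_per_patient)
  truth <- character(n_cells)
  counts <- matrix(0L, nrow = cfg$n_genes, ncol = n_cells)
  lib <- stats::rlnorm(n_cells, 0, cfg$libsize_lognormal_sd)
  for (p in seq_len(cfg$n_patients)) {
    idx <- which(cell_patient == patients[p])
    truth[idx] <- sample(cfg$cell_types, length(idx), replace = TRUE,
                         prob = cfg$cell_type_props[p, ])
    for (cell in idx) {
      mu <- type_mu[, truth[cell]] * lib[cell]
      if (truth[cell] %in% cfg$tumor_types) mu <- mu * exp(shifts[, p])
      counts[, cell] <- stats::rnbinom(cfg$n_genes, mu = mu,
                                       size = cfg$nb_dispersion)
    }
  }
  barcodes <- sprintf("cell%05d", seq_len(n_cells))
  dimnames(counts) <- list(genes, barcodes)
  meta <- data.frame(barcode = barcodes,
                     sample_id = cell_patient,
                     patient_id = cell_patient,
                     tissue = "primary",
                     stringsAsFactors = FALSE)
  list(matrix = new_count_matrix(counts, meta),
       truth = stats::setNames(truth, barcodes),
       marker_panel = marker_panel)
}

#' Configuration for the bulk-cohort survival simulator
#'
#' Each patient carries a standard-normal latent signature level; the
#' expression of the signature genes is that latent plus gene-level noise,
#' and survival is exponential with a hazard increasing in the latent.
#' `beta` is the planted log hazard ratio contrasting patients in the top
#' versus bottom quartile of the latent: internally the per-unit-latent
#' coefficient is `beta / (8 * dnorm(qnorm(0.75)))`, the expected
#' top-minus-bottom quartile mean contrast of a standard normal, so the
#' quartile-stratified analysis targets `exp(beta)` directly. Censoring is
#' independent exponential with its rate solved numerically so the
#' expected censored fraction equals `censor_rate`.
#'
#' @param n_patients Cohort size.
#' @param n_genes Total genes (signature genes plus iid-noise background).
#' @param signature_genes Names of the planted signature genes.
#' @param beta Planted top-vs-bottom-quartile log hazard ratio.
#' @param baseline_hazard Baseline exponential event rate (per day;
#'   default ~ median survival of 500 days at the latent's mean).
#' @param censor_rate Expected fraction of censored patients, in [0, 1].
#' @param noise_sd SD of the per-gene expression noise around the latent.
#' @param expr_location Additive location of expression values (log-scale
#'   units; medians are location-invariant, carried for realism).
#' @param seed Integer seed.
#' @return A validated `BulkSimConfig` list.
#' @export
bulk_sim_config <- function(n_patients = 200,
                            n_genes = 100,
                            signature_genes = sprintf("SIG%02d", 1:20),
                            beta = log(2.76),
                            baseline_hazard = log(2) / 500,
                            censor_rate = 0.3,
                            noise_sd = 1,
                            expr_location = 5,
                            seed = 1L) {
  if (!is.finite(beta)) stop("beta must be finite")
  if (censor_rate < 0 || censor_rate > 1) stop("censor_rate must be in [0, 1]")
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (length(signature_genes) < 1 || length(signature_genes) > n_genes) {
    stop("signature_genes must be non-empty and fit in the gene universe")
  }
  if (n_patients < 8) stop("n_patients must be at least 8")
  structure(list(
    n_patients = n_patients, n_genes = n_genes,
    signature_genes = signature_genes, beta = beta,
    baseline_hazard = baseline_hazard, censor_rate = censor_rate,
    noise_sd = noise_sd, expr_location = expr_location,
    seed = as.integer(seed)), class = "BulkSimConfig")
}

# expected top-minus-bottom quartile mean contrast of N(0,1)
.quartile_contrast <- 8 * stats::dnorm(stats::qnorm(0.75))

#' Simulate a bulk cohort with a planted signature-dependent hazard
#'
#' @param cfg A `BulkSimConfig` from [bulk_sim_config()].
#' @return List with `cohort` (a `BulkCohort`) and `truth` (per-patient
#'   latent signature level).
#' @export
simulate_bulk <- function(cfg) {
  stopifnot(inherits(cfg, "BulkSimConfig"))
  set.seed(cfg$seed)
  n <- cfg$n_patients
  z <- stats::rnorm(n)
  genes <- c(cfg$signature_genes,
             sprintf("BG%03d", seq_len(cfg$n_genes - length(cfg$signature_genes))))
  k <- length(cfg$signature_genes)
  expr <- matrix(stats::rnorm(n * cfg$n_genes, sd = 1), nrow = n,
                 dimnames = list(sprintf("PT%03d", seq_len(n)), genes))
  expr[, seq_len(k)] <- z + matrix(stats::rnorm(n * k, sd = cfg$noise_sd),
                                   nrow = n)
  expr <- expr + cfg$expr_location

  rate <- cfg$baseline_hazard * exp(cfg$beta / .quartile_contrast * z)
  t_event <- stats::rexp(n, rate = rate)
  if (cfg$censor_rate <= 0) {
    os_time <- t_event
    os_event <- rep(1L, n)
  } else if (cfg$censor_rate >= 1) {
    os_time <- stats::rexp(n, rate = mean(rate))
    os_event <- rep(0L, n)
  } else {
    # P(C < T) = mu / (mu + rate_i) for exponential censoring at rate mu;
    # solve mean over patients = censor_rate
    f <- function(mu) mean(mu / (mu + rate)) - cfg$censor_rate
    mu <- stats::uniroot(f, lower = 1e-12, upper = 1e6 * max(rate),
                         tol = 1e-12)$root
    t_cens <- stats::rexp(n, rate = mu)
    os_event <- as.integer(t_event <= t_cens)
    os_time <- pmin(t_event, t_cens)
  }
  clin <- data.frame(patient_id = rownames(expr),
                     os_time = os_time, os_event = os_event,
                     stringsAsFactors = FALSE)
  list(cohort = new_bulk_cohort(expr, clin),
       truth = stats::setNames(z, rownames(expr)))
}
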