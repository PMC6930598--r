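#' Simulate a reversed-phase TLC plate
#'
#' Draws per-compound true retention lines `R_M = rm0 - m C`, adds
#' homoscedastic Gaussian noise on the R_M scale, and back-transforms to
#' retardation factors `R_F = 1 / (1 + 10^R_M)`. Default parameter ranges
#' mirror the isoxazolone series on C8 plates (intercepts around 1-3.5,
#' hydrophobic constants around 2-4, methanol fractions 0.4-0.9).
#'
#' @param n_compounds Number of simulated compounds.
#' @param fractions Modifier volume fractions, strictly inside (0, 1).
#' @param rm0_range,m_range Uniform sampling ranges of the true intercepts
#'   and slope magnitudes.
#' @param sigma SD of the Gaussian noise on R_M (log units).
#' @param seed Integer seed; the generator is a deterministic function of
#'   it.
#' @return A list: `rf` (tibble `compound` + one R_F column per fraction),
#'   `fractions`, and `truth` (tibble `compound`, `rm0`, `m`, plus `sigma`
#'   and `seed`).
#' @export
gen_tlc_plate <- function(n_compounds = 26, fractions = seq(0.4, 0.9, by = 0.1),
                          rm0_range = c(1, 3.5), m_range = c(1.8, 4.2),
                          sigma = 0.05, seed = 1) {
  if (any(fractions <= 0 | fractions >= 1)) abort("fractions must lie in (0, 1)")
  with_local_seed(seed, {
    rm0 <- runif(n_compounds, rm0_range[1], rm0_range[2])
    m <- runif(n_compounds, m_range[1], m_range[2])
    rm <- outer(rm0, rep(1, length(fractions))) -
      outer(m, fractions) +
      matrix(rnorm(n_compounds * length(fractions), sd = sigma),
             n_compounds)
    rf <- 1 / (1 + 10^rm)
    clipped <- rf <= 0 | rf >= 1
    if (any(rowSums(!clipped) == 0)) {
      abort("parameter ranges put every R_F outside (0, 1)")
    }
    colnames(rf) <- formatC(fractions, format = "f", digits = 2)
    list(
      rf = dplyr::bind_cols(tibble::tibble(compound = seq_len(n_compounds)),
                            tibble::as_tibble(rf)),
      fractions = fractions,
      truth = tibble::tibble(compound = seq_len(n_compounds), rm0 = rm0,
                             m = m, sigma = sigma, seed = seed),
      clipped = which(clipped, arr.ind = TRUE)
    )
  })
}

#' Simulate a two-gradient HPLC experiment
#'
#' Draws per-compound true `(log k_w, S)` pairs, evaluates the LSS forward
#' model under two gradient geometries, and optionally perturbs the
#' retention times with Gaussian timing noise. Default geometry matches
#' the packaged instrument constants (20-98% gradient, dead time 1.401
#' min, dwell time 0.780 min, gradient times 20 and 40 min).
#'
#' @param n_compounds Number of simulated compounds.
#' @param logkw_range,s_range Uniform sampling ranges of the true
#'   parameters.
#' @param run1,run2 The two [gradient_run()] geometries.
#' @param sigma Timing noise SD in minutes (0 = noiseless).
#' @param seed Integer seed.
#' @return A list: `data` (tibble `compound`, `tR1`, `tR2`), `run1`,
#'   `run2`, and `truth` (tibble `compound`, `logkw`, `S`, `sigma`,
#'   `seed`).
#' @export
gen_gradient_pair <- function(n_compounds = 26, logkw_range = c(2, 4),
                              s_range = c(2.5, 5),
                              run1 = gradient_run(20), run2 = gradient_run(40),
                              sigma = 0, seed = 1) {
  with_local_seed(seed, {
    logkw <- runif(n_compounds, logkw_range[1], logkw_range[2])
    S <- runif(n_compounds, s_range[1], s_range[2])
    tR1 <- lss_retention_time(logkw, S, run1) + rnorm(n_compounds, sd = sigma)
    tR2 <- lss_retention_time(logkw, S, run2) + rnorm(n_compounds, sd = sigma)
    list(
      data = tibble::tibble(compound = seq_len(n_compounds), tR1 = tR1,
                            tR2 = tR2),
      run1 = run1, run2 = run2,
      truth = tibble::tibble(compound = seq_len(n_compounds), logkw = logkw,
                             S = S, sigma = sigma, seed = seed)
    )
  })
}

#' Simulate MEKC migration times
#'
#' Draws true retention factors and inverts the MEKC retention equation to
#' produce analyte migration times between the EOF and micelle markers:
#' `tR = tEOF (1 + k) / (1 + k tEOF / tMC)`. [terabe_logk()] round-trips
#' the generated times to the true `log k` exactly.
#'
#' @param n_compounds Number of simulated analytes.
#' @param k_range Uniform sampling range of true retention factors
#'   (positive).
#' @param tEOF,tMC Marker migration times, `0 < tEOF < tMC`.
#' @param seed Integer seed.
#' @return A list: `data` (tibble `compound`, `tR`, `tEOF`, `tMC`) and
#'   `truth` (tibble `compound`, `k`, `logk`, `seed`).
#' @export
gen_mekc_run <- function(n_compounds = 26, k_range = c(0.3, 3),
                         tEOF = 4, tMC = 20, seed = 1) {
  if (tEOF <= 0 || tMC <= tEOF) abort("need 0 < tEOF < tMC")
  if (any(k_range <= 0)) abort("k_range must be positive")
  with_local_seed(seed, {
    k <- runif(n_compounds, k_range[1], k_range[2])
    tR <- tEOF * (1 + k) / (1 + k * tEOF / tMC)
    if (any(tR >= tMC - 1e-9)) abort("k outside the representable migration window")
    list(
      data = tibble::tibble(compound = seq_len(n_compounds), tR = tR,
                            tEOF = tEOF, tMC = tMC),
      truth = tibble::tibble(compound = seq_len(n_compounds), k = k,
                             logk = log10(k), seed = seed)
    )
  })
}

#' Simulate a descriptor matrix with a planted linear signal
#'
#' Generates standard-normal descriptors, plants `k_informative` of them
#' in a linear response `y = X beta + noise` (coefficients drawn uniformly
#' from `beta_range` with random sign), and optionally duplicates a
#' fraction of columns with small jitter to exercise the redundancy
#' filter of [preselect_descriptors()].
#'
#' @param n Samples (compounds).
#' @param p Descriptors before duplication.
#' @param k_informative Number of planted informative descriptors
#'   (`<= p`).
#' @param beta_range Magnitude range of the planted coefficients.
#' @param sigma Response noise SD.
#' @param correlated_fraction Fraction of columns duplicated with jitter
#'   (appended as `<name>_dup`).
#' @param seed Integer seed.
#' @return A list: `X` (tibble `compound` + descriptors `D1..`), `y`, and
#'   `truth` (planted descriptor names, coefficients, `sigma`, `seed`).
#' @export
gen_descriptor_dataset <- function(n = 26, p = 30, k_informative = 3,
                                   beta_range = c(0.5, 1.5), sigma = 0.1,
                                   correlated_fraction = 0, seed = 1) {
  if (k_informative > p) abort("k_informative must not exceed p")
  with_local_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("D", seq_len(p))))
    planted <- sort(sample.int(p, k_informative))
    beta <- runif(k_informative, beta_range[1], beta_range[2]) *
      sample(c(-1, 1), k_informative, replace = TRUE)
    y <- drop(X[, planted, drop = FALSE] %*% beta) + rnorm(n, sd = sigma)
    if (correlated_fraction > 0) {
      dup <- sample.int(p, max(1, round(correlated_fraction * p)))
      Xd <- X[, dup, drop = FALSE] +
        matrix(rnorm(n * length(dup), sd = 0.01), n)
      colnames(Xd) <- paste0(colnames(X)[dup], "_dup")
      X <- cbind(X, Xd)
    }
    list(
      X = dplyr::bind_cols(tibble::tibble(compound = seq_len(n)),
                           tibble::as_tibble(X)),
      y = y,
      truth = list(planted = paste0("D", planted), beta = beta,
                   sigma = sigma, seed = seed)
    )
  })
}
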