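#' Simulate a multimodal study with known ground truth
#'
#' Generates a metadata table plus `J` omics matrices sharing one sample
#' order, with a planted group effect on a known subset of features per
#' dataset, so every downstream stage can be tested without external data.
#'
#' Gaussian mode: null features are iid N(0, 1); planted features are
#' N(-delta/2, 1) in the reference group and N(+delta/2, 1) in the other
#' group(s), i.e. the group means differ by `delta` feature standard
#' deviations. Negative-binomial mode: counts with baseline log-mean
#' `nb_log_mean`, dispersion `nb_dispersion`, and a log2 fold-change of
#' `delta` on the planted features (for the count/precision-weight pipeline).
#' Metadata includes the response, a categorical batch variable, and null
#' numeric/categorical covariates. An optional batch shift adds
#' `batch_shift` (in feature-sd units) to every feature for samples in batch
#' "b2", planting a dominant variance axis detectable by PCA.
#'
#' An optional equicorrelation `rho` within consecutive blocks of 10 features
#' stresses grouped selection in the elastic net.
#'
#' @param n total samples.
#' @param prop group proportions (named or not; length = number of groups).
#' @param p integer vector: features per dataset (length J).
#' @param q integer vector: planted features per dataset.
#' @param delta effect size in feature-sd units (gaussian) or log2 fold-change
#'   (counts).
#' @param noise `"gaussian"` or `"negative_binomial"`.
#' @param nb_dispersion,nb_log_mean negative-binomial parameters (dispersion
#'   `size = 1/dispersion`; baseline mean `exp(nb_log_mean)`).
#' @param batch_shift additive shift for batch "b2" (0 disables).
#' @param rho within-block (size 10) equicorrelation for gaussian features.
#' @param seed integer seed; the output is fully determined by it.
#' @return list with `study` (an `omx_study`) and `truth` (planted feature
#'   names per dataset, group labels, batch labels).
#' @export
simulate_study <- function(n = 100, prop = c(control = 0.5, case = 0.5),
                           p = c(400, 400), q = c(10, 10), delta = 1,
                           noise = c("gaussian", "negative_binomial"),
                           nb_dispersion = 0.2, nb_log_mean = log(200),
                           batch_shift = 0, rho = 0, seed = 1) {
  noise <- match.arg(noise)
  if (abs(sum(prop) - 1) > 1e-8) stopf("group proportions must sum to 1")
  if (any(q > p)) stopf("planted features q must not exceed p")
  if (delta < 0) stopf("delta must be >= 0")
  J <- length(p)
  if (length(q) != J) stopf("p and q must have the same length")
  groups <- names(prop)
  if (is.null(groups)) groups <- paste0("g", seq_along(prop))

  set.seed(seed)
  counts_per_group <- diff(round(cumsum(c(0, prop)) * n))
  if (any(counts_per_group < 2L)) stopf("infeasible spec: a group has < 2 samples")
  y <- factor(rep(groups, counts_per_group), levels = groups)
  batch <- factor(sample(rep(c("b1", "b2"), length.out = n)))
  age <- round(stats::rnorm(n, 55, 10), 1)
  score <- round(stats::runif(n, 0, 100), 2)
  sex <- sample(c("F", "M"), n, replace = TRUE)

  ## signed group effect: reference group low, others high
  sgn <- ifelse(y == groups[1L], -0.5, +0.5)
  truth_features <- vector("list", J)
  datasets <- vector("list", J)
  for (j in seq_len(J)) {
    nm <- paste0("ds", j)
    feat <- sprintf("%s_f%04d", nm, seq_len(p[j]))
    planted <- feat[seq_len(q[j])]
    if (noise == "gaussian") {
      x <- matrix(stats::rnorm(n * p[j]), n, p[j])
      if (rho > 0) {
        ## block equicorrelation via a shared block factor
        blocks <- ceiling(seq_len(p[j]) / 10)
        z <- matrix(stats::rnorm(n * max(blocks)), n, max(blocks))
        x <- sqrt(1 - rho) * x + sqrt(rho) * z[, blocks, drop = FALSE]
      }
      if (q[j] > 0) x[, seq_len(q[j])] <- x[, seq_len(q[j]), drop = FALSE] + sgn * delta
      if (batch_shift > 0) x <- x + ifelse(batch == "b2", batch_shift, 0)
      colnames(x) <- feat
      datasets[[j]] <- omics_from_df(x, nm)
    } else {
      lfc <- sgn * delta           # log2 fold-change split across groups
      mu <- exp(nb_log_mean + outer(rep(1, n), stats::rnorm(p[j], 0, 0.5)))
      mu[, seq_len(q[j])] <- mu[, seq_len(q[j]), drop = FALSE] * 2^lfc
      x <- matrix(stats::rnbinom(n * p[j], mu = mu, size = 1 / nb_dispersion),
                  n, p[j])
      colnames(x) <- feat
      datasets[[j]] <- omics_from_df(x, nm)
    }
    truth_features[[j]] <- planted
    names(truth_features)[j] <- nm
  }

  md <- data.frame(group = as.character(y), batch = as.character(batch),
                   age = age, score = score, sex = sex,
                   stringsAsFactors = FALSE)
  lm <- metadata_from_df(md, "group", groups[1L])
  study <- assemble_study(lm$metadata, lm$response, datasets)
  truth <- list(planted = truth_features, group = as.character(y),
                batch = as.character(batch))
  list(study = study, truth = truth)
}

#' Simulate a complementary-signal two-modality study
#'
#' Cases are split into two latent subtypes; modality 1 carries signal only
#' for subtype-A cases, modality 2 only for subtype-B cases, so no single
#' modality can classify all cases but the averaged ensemble can.
#'
#' @param n samples (half cases, half controls).
#' @param p features per modality.
#' @param q planted features per modality.
#' @param delta mean shift (feature-sd units) in the responsive subtype.
#' @param seed integer seed.
#' @return list with `study` and `truth` (planted names, subtype labels).
#' @export
simulate_complementary_study <- function(n = 120, p = 200, q = 10, delta = 2.5,
                                         seed = 1) {
  set.seed(seed)
  n_case <- n %/% 2
  y <- factor(rep(c("control", "case"), c(n - n_case, n_case)),
              levels = c("control", "case"))
  subtype <- rep("none", n)
  case_idx <- which(y == "case")
  half <- length(case_idx) %/% 2
  subtype[case_idx[seq_len(half)]] <- "A"
  subtype[case_idx[-seq_len(half)]] <- "B"
  datasets <- vector("list", 2L)
  truth_features <- list()
  for (j in 1:2) {
    nm <- paste0("ds", j)
    feat <- sprintf("%s_f%04d", nm, seq_len(p))
    x <- matrix(stats::rnorm(n * p), n, p)
    responsive <- subtype == c("A", "B")[j]
    x[responsive, seq_len(q)] <- x[responsive, seq_len(q), drop = FALSE] + delta
    colnames(x) <- feat
    datasets[[j]] <- omics_from_df(x, nm)
    truth_features[[nm]] <- feat[seq_len(q)]
  }
  md <- data.frame(group = as.character(y), stringsAsFactors = FALSE)
  lm <- metadata_from_df(md, "group", "control")
  study <- assemble_study(lm$metadata, lm$response, datasets)
  list(study = study, truth = list(planted = truth_features, subtype = subtype))
}

#' Simulate a drug-reversal fixture with one planted antisignature
#'
#' Builds a disease signature (up/down gene lists) plus up/down perturbation
#' gene-set collections in which exactly one perturbation's down-set is
#' enriched for the disease up-genes and its up-set for the disease
#' down-genes; the remaining perturbations draw members uniformly from the
#' universe.
#'
#' @param n_sets number of perturbations (>= 2).
#' @param universe_size genes in the universe.
#' @param sig_size genes per direction in the disease signature.
#' @param set_size genes per perturbation set.
#' @param planted if FALSE, the planted overlap is omitted (null fixture).
#' @param seed integer seed.
#' @return list: `up`, `down` (query gene lists), `pert_up`, `pert_down`
#'   (`omx_genesets`), `universe`, `planted_name`.
#' @export
simulate_reversal_fixture <- function(n_sets = 50, universe_size = 1000,
                                      sig_size = 40, set_size = 50,
                                      planted = TRUE, seed = 1) {
  if (n_sets < 2) stopf("n_sets must be >= 2")
  set.seed(seed)
  universe <- sprintf("G%04d", seq_len(universe_size))
  sig <- sample(universe, 2 * sig_size)
  up <- sig[seq_len(sig_size)]
  down <- sig[-seq_len(sig_size)]
  pert_names <- sprintf("drug_%03d", seq_len(n_sets))
  mk_sets <- function(anti) {
    sets <- lapply(seq_len(n_sets), function(i) {
      if (planted && i == 1L) {
        ## planted antisignature: mostly overlapping the opposite direction
        k <- round(0.6 * set_size)
        c(sample(anti, min(k, length(anti))),
          sample(setdiff(universe, anti), set_size - min(k, length(anti))))
      } else sample(universe, set_size)
    })
    names(sets) <- pert_names
    sets
  }
  pert_down <- genesets_from_list(mk_sets(up), name = "pert_down")
  pert_up <- genesets_from_list(mk_sets(down), name = "pert_up")
  list(up = up, down = down, pert_up = pert_up, pert_down = pert_down,
       universe = universe, planted_name = if (planted) pert_names[1L] else NA)
}
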