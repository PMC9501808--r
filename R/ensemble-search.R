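#' Sum-constrained non-negative least squares populations
#'
#' Populations for a candidate set of conformers are the non-negative
#' least-squares solution of the weighted system augmented by one row with a
#' very high equal value `lambda` in every column and in the data vector,
#' which enforces the sum-to-one constraint to a `lambda`-controlled
#' tolerance. The active-set solver returns exact zeros, which defines the
#' effective ensemble size.
#'
#' @param submatrix k x n matrix whose rows are the candidate members'
#'   predictions (rows of the prediction matrix).
#' @param data length-n data vector.
#' @param weights per-record weights (default 1).
#' @param lambda constraint row value; default `1e4 * max(abs(weighted
#'   submatrix))`, high enough for a sum error below 1e-6.
#' @return non-negative populations summing to 1 (within tolerance), with
#'   `rmsd` (weighted residual RMSD) and `n_eff` attributes.
#' @export
constrained_nnls <- function(submatrix, data, weights = NULL, lambda = NULL) {
  submatrix <- rbind(submatrix)
  if (all(submatrix == 0)) stop("all-zero prediction submatrix")
  n <- ncol(submatrix)
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(lambda)) lambda <- 1e4 * max(abs(submatrix * rep(weights, each = nrow(submatrix))))
  res <- .nnls_populations_cpp(t(submatrix), data, weights,
                               seq_len(nrow(submatrix)), lambda)
  structure(drop(res$populations), rmsd = res$rmsd, n_eff = res$n_eff)
}

#' Ensemble fitness embedding the Bayesian information criterion
#'
#' For normally distributed errors with scatter estimated by the RMSD, the
#' BIC of an ensemble model with `k = params_per_member * n_eff` free
#' parameters is `n ln(rmsd^2) + k ln(n)`. The fitness
#' \deqn{f = rmsd \cdot n^{k/(2n)}}
#' is the monotone transform `exp(BIC / 2n)` of that BIC: it preserves the
#' BIC ordering while staying on the intuitive scale of an RMSD (it equals
#' the RMSD at `k = 0`). Lower is better. Each effective member carries 7
#' parameters: 6 rigid-body degrees of freedom plus 1 population.
#'
#' @param rmsd weighted, dimensionless data RMSD of the ensemble model.
#' @param n_eff effective ensemble size (members with nonzero population).
#' @param n_data number of data points.
#' @param params_per_member model parameters per effective member.
#' @return the fitness.
#' @export
ensemble_score <- function(rmsd, n_eff, n_data, params_per_member = 7) {
  k <- params_per_member * n_eff
  if (any(k >= n_data)) stop("model dimension k must be below n_data")
  if (any(rmsd < 0)) stop("rmsd must be non-negative")
  rmsd * n_data^(k / (2 * n_data))
}

#' Genetic-algorithm configuration
#'
#' @param size nominal ensemble size (members per candidate; the effective
#'   size after NNLS is usually smaller).
#' @param generations number of generations.
#' @param population number of candidate ensembles per generation.
#' @param elite_frac fraction of best candidates copied unchanged (ensures a
#'   non-increasing best fitness).
#' @param temperature rank scale of the exponential parent-selection
#'   probability `P(rank) ~ exp(-rank / temperature)`.
#' @param crossover_rate probability that a child combines two parents by
#'   uniform crossover (else it clones one parent).
#' @param mutation_rate per-slot probability of replacing a member with a
#'   random pool index.
#' @param seed optional integer seed making the run reproducible.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(size = 20, generations = 200, population = 200,
                      elite_frac = 0.05, temperature = population / 5,
                      crossover_rate = 1, mutation_rate = 1 / size,
                      seed = NULL) {
  stopifnot(size >= 1, generations >= 1, population >= 2,
            elite_frac > 0, elite_frac <= 1, temperature > 0,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  structure(list(size = size, generations = generations,
                 population = population, elite_frac = elite_frac,
                 temperature = temperature, crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate, seed = seed),
            class = "ga_config")
}

.make_ensemble <- function(members, populations, rmsd, n_eff, n_data,
                           params_per_member = 7) {
  keep <- order(members)
  structure(list(members = members[keep], populations = populations[keep],
                 rmsd = rmsd, n_eff = n_eff,
                 fitness = ensemble_score(rmsd, n_eff, n_data, params_per_member),
                 n_data = n_data),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("ensemble: n_eff = %d (of %d members), rmsd = %.4g, fitness = %.4g\n",
              x$n_eff, length(x$members), x$rmsd, x$fitness))
  on <- x$populations > 0
  cat("members:", paste(sprintf("%d (%.3f)", x$members[on], x$populations[on]),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate one candidate ensemble
#'
#' Collapses duplicate member indices, assigns populations by
#' [constrained_nnls()], and scores with [ensemble_score()].
#'
#' @param members pool indices.
#' @param pred_matrix n_conformer x n_data prediction matrix.
#' @param data,weights data vector and per-record weights.
#' @param lambda sum-constraint row value (default as in
#'   [constrained_nnls()]).
#' @param params_per_member see [ensemble_score()].
#' @return an `ensemble` object.
#' @export
evaluate_ensemble <- function(members, pred_matrix, data, weights = NULL,
                              lambda = NULL, params_per_member = 7) {
  members <- sort(unique(as.integer(members)))
  n <- ncol(pred_matrix)
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(lambda)) lambda <- 1e4 * max(abs(pred_matrix * rep(weights, each = nrow(pred_matrix))))
  res <- .nnls_populations_cpp(t(pred_matrix), data, weights, members, lambda)
  .make_ensemble(members, drop(res$populations), res$rmsd, res$n_eff, n,
                 params_per_member)
}

#' Evolve ensembles with an elitist genetic algorithm
#'
#' Candidate solutions are fixed-size member-index sets. Each generation the
#' best `elite_frac` are copied unchanged; parents are drawn with probability
#' proportional to `exp(-rank / temperature)`; children are produced by
#' uniform crossover of the two parents' index vectors and per-slot random
#' mutation. Candidates are scored by sum-constrained NNLS populations and
#' the BIC-embedding fitness, so the effective model dimension evolves with
#' the candidates. The best fitness is non-increasing across generations.
#'
#' @param pred_matrix n_conformer x n_data prediction matrix.
#' @param data,weights data vector and per-record weights.
#' @param config a [ga_config()].
#' @param params_per_member see [ensemble_score()].
#' @return list with `best` (an `ensemble`), `history` (data.frame of best
#'   fitness/rmsd/n_eff per generation), and `final_population` (member
#'   matrix of the last generation).
#' @export
evolve_ensembles <- function(pred_matrix, data, weights = NULL,
                             config = ga_config(), params_per_member = 7) {
  n_conf <- nrow(pred_matrix)
  n_data <- ncol(pred_matrix)
  if (n_conf < config$size) stop("pool smaller than the nominal ensemble size")
  if (is.null(weights)) weights <- rep(1, n_data)
  if (!is.null(config$seed)) set.seed(config$seed)
  lambda <- 1e4 * max(abs(pred_matrix * rep(weights, each = n_conf)))
  predT <- t(pred_matrix)

  npop <- config$population
  members <- matrix(sample.int(n_conf, config$size * npop, replace = TRUE),
                    nrow = config$size)
  n_elite <- max(1L, round(config$elite_frac * npop))
  history <- data.frame(generation = integer(), fitness = numeric(),
                        rmsd = numeric(), n_eff = integer())
  best <- NULL
  for (gen in seq_len(config$generations)) {
    sc <- .score_ensembles_cpp(predT, data, weights, members, lambda)
    fit <- ensemble_score(sc$rmsd, sc$n_eff, n_data, params_per_member)
    ord <- order(fit)
    ibest <- ord[1]
    if (is.null(best) || fit[ibest] < best$fitness) {
      best <- .make_ensemble(sc$members[[ibest]], sc$populations[[ibest]],
                             sc$rmsd[ibest], sc$n_eff[ibest], n_data,
                             params_per_member)
    }
    history <- rbind(history, data.frame(generation = gen,
                                         fitness = best$fitness,
                                         rmsd = best$rmsd,
                                         n_eff = best$n_eff))
    if (gen == config$generations) break
    elites <- members[, ord[seq_len(n_elite)], drop = FALSE]
    # exponential rank selection on the sorted candidates
    pr <- exp(-(seq_len(npop) - 1) / config$temperature)
    n_child <- npop - n_elite
    pa <- sample.int(npop, n_child, replace = TRUE, prob = pr)
    pb <- sample.int(npop, n_child, replace = TRUE, prob = pr)
    A <- members[, ord[pa], drop = FALSE]
    B <- members[, ord[pb], drop = FALSE]
    cross <- matrix(stats::runif(config$size * n_child) < 0.5,
                    nrow = config$size)
    children <- ifelse(cross, A, B)
    do_cross <- stats::runif(n_child) < config$crossover_rate
    children[, !do_cross] <- A[, !do_cross]
    mut <- matrix(stats::runif(config$size * n_child) < config$mutation_rate,
                  nrow = config$size)
    children[mut] <- sample.int(n_conf, sum(mut), replace = TRUE)
    members <- cbind(elites, children)
  }
  list(best = best, history = history, final_population = members)
}

#' Bootstrap spread of the fitness difference between two ensembles
#'
#' Resamples the data records with replacement, re-evaluates both ensembles'
#' weighted RMSD (members and populations held fixed) and fitness on every
#' resample, and returns the standard deviation of the fitness difference.
#' Two ensembles closer in fitness than about twice this value cannot be
#' distinguished given the data scatter.
#'
#' @param ens_a,ens_b `ensemble` objects scored on the same data.
#' @param pred_matrix,data,weights as in [evolve_ensembles()].
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param seed optional integer seed.
#' @param params_per_member see [ensemble_score()].
#' @return standard deviation of the fitness difference, with the resampled
#'   differences in attribute `"deltas"`.
#' @export
fitness_difference_sigma <- function(ens_a, ens_b, pred_matrix, data,
                                     weights = NULL, n_boot = 10000,
                                     seed = NULL, params_per_member = 7) {
  if (n_boot < 100) stop("n_boot must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(pred_matrix)
  if (is.null(weights)) weights <- rep(1, n)
  sq_res <- function(e) {
    pred <- drop(crossprod(pred_matrix[e$members, , drop = FALSE], e$populations))
    (weights * (data - pred))^2
  }
  ra <- sq_res(ens_a)
  rb <- sq_res(ens_b)
  ka <- params_per_member * ens_a$n_eff
  kb <- params_per_member * ens_b$n_eff
  deltas <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    fa <- sqrt(mean(ra[idx])) * n^(ka / (2 * n))
    fb <- sqrt(mean(rb[idx])) * n^(kb / (2 * n))
    fa - fb
  }, numeric(1))
  structure(stats::sd(deltas), deltas = deltas)
}

#' Summary statistics of repeated evolutionary runs
#'
#' @param fitnesses best-fitness values from independent [evolve_ensembles()]
#'   runs (>= 2).
#' @param sigma_delta optional bootstrap fitness-difference spread from
#'   [fitness_difference_sigma()]; when given, the 2-sigma significance
#'   threshold below the best fitness is reported.
#' @return list with `mean`, `sd`, `min`, `n`, and (if `sigma_delta` given)
#'   `significance_threshold = min - 2 * sigma_delta`.
#' @export
run_statistics <- function(fitnesses, sigma_delta = NULL) {
  if (length(fitnesses) < 2) stop("need at least 2 runs")
  out <- list(mean = mean(fitnesses), sd = stats::sd(fitnesses),
              min = min(fitnesses), n = length(fitnesses))
  if (!is.null(sigma_delta)) {
    out$significance_threshold <- out$min - 2 * sigma_delta
  }
  out
}
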