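#' Default driver mutation rates
#'
#' Per-group Bernoulli mutation probabilities for four driver-like genes:
#' two FLT3/NPM1-like genes strongly enriched in the short-lived group and
#' two IDH2/MT-CYB-like genes mildly enriched in the long-lived group,
#' mirroring the empirical frequencies in the DNMT3A-mutant TCGA cohort
#' (FLT3 20/24 vs 1/27, NPM1 21/24 vs 7/27, IDH2 0/24 vs 5/27,
#' MT-CYB 0/24 vs 4/27; an exact zero is replaced by 0.01 so every profile
#' stays stochastic).
#'
#' @return data frame with columns `gene`, `p_short`, `p_long`.
#' @export
default_driver_rates <- function() {
  data.frame(
    gene = c("FLT3", "NPM1", "IDH2", "MT-CYB"),
    p_short = c(20 / 24, 21 / 24, 0.01, 0.01),
    p_long = c(1 / 27, 7 / 27, 5 / 27, 4 / 27),
    stringsAsFactors = FALSE
  )
}

#' Synthetic cohort configuration
#'
#' Parameterizes [generate_cohort()].  Defaults are tuned to the study
#' cohort this pipeline targets: 51 DNMT3A-mutant patients averaging about
#' 13.3 mutated genes out of 1,890, a 24:27 short:long split, 15,623
#' expression genes with a 260-gene differentially expressed signature
#' driven by a planted sparse linear network, 514 miRNAs of which a subset
#' is coupled to host genes, and 42 of 51 patients carrying the miRNA layer.
#'
#' @param n_patients number of patients.
#' @param group_proportion fraction of patients in the latent short-lived
#'   group.
#' @param n_genes number of mutable genes (including the constitutive
#'   DNMT3A column and the drivers).
#' @param driver_rates data frame `gene`, `p_short`, `p_long` of per-group
#'   driver mutation probabilities.
#' @param background_rate Bernoulli mutation probability for non-driver
#'   genes; either a single rate or a length-2 vector `(short, long)`.
#'   The default reproduces the cohort's group-dependent mutational burden
#'   (median mutated genes about 10.5 in the short-lived and 17 in the
#'   long-lived group, overall mean about 13.3).
#' @param hazard_short,hazard_long exponential event hazards (1/days) of
#'   the two groups.
#' @param censor_rate exponential censoring hazard (1/days).
#' @param n_expr_genes number of expression genes.
#' @param n_signature number of planted differentially expressed genes.
#' @param effect_size mean log2 expression shift between the groups.
#' @param noise_sd residual standard deviation (log2 units).
#' @param n_mirnas number of miRNAs.
#' @param n_host_coupled number of miRNAs coupled to a host gene.
#' @param host_coupling_r target miRNA-host correlation in `[0, 1]`.
#' @param mirna_missing_fraction fraction of patients lacking the miRNA
#'   layer.
#' @param network_density fraction of nonzero regulator-target links in the
#'   planted network.
#' @param network_weight_range magnitude range `(lo, hi)` of planted link
#'   weights (sign drawn with equal probability).
#' @param network_regulator_fraction fraction of signature genes acting as
#'   regulators; the rest are network targets.
#' @param seed integer seed governing all layers (fixed substream order:
#'   labels+mutations, planted network, expression, miRNA, survival,
#'   missingness).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 51, group_proportion = 24 / 51,
                          n_genes = 1890,
                          driver_rates = default_driver_rates(),
                          background_rate = c(0.0042, 0.0082),
                          hazard_short = 1 / 250, hazard_long = 1 / 900,
                          censor_rate = 1 / 1500,
                          n_expr_genes = 15623, n_signature = 260,
                          effect_size = 1, noise_sd = 0.5,
                          n_mirnas = 514, n_host_coupled = 50,
                          host_coupling_r = 0.6,
                          mirna_missing_fraction = 9 / 51,
                          network_density = 0.05,
                          network_weight_range = c(1, 2),
                          network_regulator_fraction = 0.3,
                          seed = 1L) {
  cfg <- list(n_patients = n_patients, group_proportion = group_proportion,
              n_genes = n_genes, driver_rates = driver_rates,
              background_rate = background_rate,
              hazard_short = hazard_short, hazard_long = hazard_long,
              censor_rate = censor_rate, n_expr_genes = n_expr_genes,
              n_signature = n_signature, effect_size = effect_size,
              noise_sd = noise_sd, n_mirnas = n_mirnas,
              n_host_coupled = n_host_coupled,
              host_coupling_r = host_coupling_r,
              mirna_missing_fraction = mirna_missing_fraction,
              network_density = network_density,
              network_weight_range = network_weight_range,
              network_regulator_fraction = network_regulator_fraction,
              seed = as.integer(seed))
  .validate_config(cfg)
  structure(cfg, class = "cohort_config")
}

.validate_config <- function(cfg) {
  chk_prob <- function(name) {
    v <- cfg[[name]]
    if (!is.numeric(v) || any(v < 0 | v > 1))
      stop("configuration error: '", name, "' must be in [0, 1]")
  }
  for (f in c("group_proportion", "background_rate", "host_coupling_r",
              "mirna_missing_fraction", "network_regulator_fraction"))
    chk_prob(f)
  for (f in c("hazard_short", "hazard_long", "censor_rate"))
    if (cfg[[f]] <= 0)
      stop("configuration error: '", f, "' must be > 0")
  if (any(cfg$driver_rates$p_short < 0 | cfg$driver_rates$p_short > 1) ||
      any(cfg$driver_rates$p_long < 0 | cfg$driver_rates$p_long > 1))
    stop("configuration error: 'driver_rates' probabilities must be in [0, 1]")
  if (cfg$n_signature > cfg$n_expr_genes)
    stop("configuration error: 'n_signature' exceeds 'n_expr_genes'")
  if (cfg$n_host_coupled > cfg$n_mirnas)
    stop("configuration error: 'n_host_coupled' exceeds 'n_mirnas'")
  if (cfg$network_density <= 0 || cfg$network_density > 1)
    stop("configuration error: 'network_density' must be in (0, 1]")
  invisible(cfg)
}

#' Plant a sparse signed regulator-target network
#'
#' Draws `round(density * n_targets * n_regulators)` links uniformly over
#' the regulator x target grid, with weight magnitudes uniform in
#' `weight_range` and signs drawn with equal probability.
#'
#' @param n_targets,n_regulators node counts (regulator and target id sets
#'   are disjoint, so no self-loops can arise).
#' @param density fraction of nonzero links in `(0, 1]`.
#' @param weight_range magnitude range `(lo, hi)`, `lo > 0`.
#' @param seed integer seed.
#' @param target_ids,regulator_ids optional node names (defaults `T1..`,
#'   `R1..`).
#' @return object of class `planted_network`: list with `targets`,
#'   `regulators`, `weights` (regulators x targets matrix) and `density`.
#' @export
plant_network <- function(n_targets, n_regulators, density,
                          weight_range = c(1, 2), seed = 1L,
                          target_ids = NULL, regulator_ids = NULL) {
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  if (weight_range[1] <= 0) stop("weight magnitude lower bound must be > 0")
  nnz <- round(density * n_targets * n_regulators)
  if (nnz < 1)
    stop("density * n_targets * n_regulators < 1: no links to plant")
  if (is.null(target_ids)) target_ids <- paste0("T", seq_len(n_targets))
  if (is.null(regulator_ids)) regulator_ids <- paste0("R", seq_len(n_regulators))
  set.seed(seed)
  cells <- sample.int(n_targets * n_regulators, nnz)
  W <- matrix(0, n_regulators, n_targets,
              dimnames = list(regulator_ids, target_ids))
  W[cells] <- stats::runif(nnz, weight_range[1], weight_range[2]) *
    sample(c(-1, 1), nnz, replace = TRUE)
  structure(list(targets = target_ids, regulators = regulator_ids,
                 weights = W, density = nnz / (n_targets * n_regulators)),
            class = "planted_network")
}

#' Edge list of a planted network
#' @param net a `planted_network`.
#' @return data frame `source`, `target`, `weight` for the nonzero links.
#' @export
planted_edges <- function(net) {
  idx <- which(net$weights != 0, arr.ind = TRUE)
  data.frame(source = net$regulators[idx[, 1]],
             target = net$targets[idx[, 2]],
             weight = net$weights[idx], row.names = NULL)
}

#' Simulate survival from group labels
#'
#' Event and censoring times are independent exponentials: the observed time
#' is their minimum and the event indicator is 1 iff the event time comes
#' first (non-informative censoring).
#'
#' @param labels named vector patient -> `"short-lived"`/`"long-lived"` (or
#'   any two labels; the one matching `"short"` gets `hazard_short`).
#' @param hazard_short,hazard_long event hazards (1/days), > 0.
#' @param censor_rate censoring hazard (1/days), > 0.
#' @param seed integer seed.
#' @return a `survival_table`.
#' @export
survival_from_labels <- function(labels, hazard_short, hazard_long,
                                 censor_rate, seed = 1L) {
  if (!length(labels)) stop("empty label vector")
  if (hazard_short <= 0 || hazard_long <= 0 || censor_rate <= 0)
    stop("hazards must be > 0")
  set.seed(seed)
  haz <- ifelse(grepl("short", labels), hazard_short, hazard_long)
  event_time <- stats::rexp(length(labels), haz)
  censor_time <- stats::rexp(length(labels), censor_rate)
  as_survival_table(data.frame(
    patient_id = names(labels),
    time = pmin(event_time, censor_time),
    event = as.integer(event_time <= censor_time)
  ))
}

#' Generate a synthetic multi-layer cohort
#'
#' Produces jointly consistent mutation, expression, miRNA and survival
#' layers with known ground truth:
#' \itemize{
#'   \item latent short/long labels at the configured proportion;
#'   \item binary mutation profiles with a constitutive DNMT3A column,
#'     group-dependent driver genes and Bernoulli background genes;
#'   \item log2 expression where signature regulators carry a +/-
#'     `effect_size`/2 group shift on a Normal(8, 2) base level, network
#'     targets are exact weighted sums of their regulators plus
#'     Gaussian(0, `noise_sd`) noise, and all remaining genes are
#'     group-independent;
#'   \item miRNAs of which `n_host_coupled` track a host gene with
#'     population correlation `host_coupling_r` and the rest are
#'     independent; a fraction of patients is flagged as missing the miRNA
#'     layer (flags, not NaNs);
#'   \item exponential survival with group-dependent hazards and
#'     independent exponential censoring.
#' }
#' The single `seed` governs all layers through a fixed substream order
#' (labels+mutations, planted network, expression, miRNA, survival,
#' missingness), so any prefix of the layers is reproducible.
#'
#' @param config a `cohort_config`.
#' @return object of class `synthetic_cohort`: list with `mutations`
#'   (patients x genes `aml_mutation_matrix`), `expression`
#'   (genes x patients), `mirna` (miRNAs x patients), `mirna_missing`
#'   (named logical), `survival` (a `survival_table`), `true_labels`,
#'   `network` (a `planted_network` over expression gene ids), `host_map`
#'   and `config`.
#' @export
generate_cohort <- function(config) {
  .validate_config(config)
  cfg <- config
  n <- cfg$n_patients
  patients <- sprintf("P%03d", seq_len(n))

  # -- substream 1: latent labels and mutation layer
  set.seed(cfg$seed)
  n_short <- round(n * cfg$group_proportion)
  labels <- rep("long-lived", n)
  labels[sample.int(n, n_short)] <- "short-lived"
  names(labels) <- patients
  short <- labels == "short-lived"

  drivers <- cfg$driver_rates
  n_background <- cfg$n_genes - nrow(drivers) - 1
  genes <- c("DNMT3A", drivers$gene,
             sprintf("BG%04d", seq_len(n_background)))
  M <- matrix(0L, n, cfg$n_genes, dimnames = list(patients, genes))
  M[, "DNMT3A"] <- 1L
  for (i in seq_len(nrow(drivers))) {
    pr <- ifelse(short, drivers$p_short[i], drivers$p_long[i])
    M[, drivers$gene[i]] <- stats::rbinom(n, 1, pr)
  }
  br <- if (length(cfg$background_rate) == 2)
    ifelse(short, cfg$background_rate[1], cfg$background_rate[2])
  else rep(cfg$background_rate, n)
  M[, -(seq_len(nrow(drivers) + 1))] <-
    stats::rbinom(n * n_background, 1, rep(br, n_background))
  class(M) <- c("aml_mutation_matrix", class(M))

  # -- substream 2: planted network over the signature genes
  expr_genes <- sprintf("G%05d", seq_len(cfg$n_expr_genes))
  sig_genes <- expr_genes[seq_len(cfg$n_signature)]
  n_reg <- max(2, round(cfg$network_regulator_fraction * cfg$n_signature))
  n_reg <- min(n_reg, cfg$n_signature - 1)
  regulators <- sig_genes[seq_len(n_reg)]
  targets <- setdiff(sig_genes, regulators)
  # at least one link even for tiny test-scale signatures
  dens <- max(cfg$network_density,
              1 / (length(targets) * length(regulators)))
  network <- plant_network(length(targets), length(regulators),
                           dens, cfg$network_weight_range,
                           seed = cfg$seed + 1L,
                           target_ids = targets, regulator_ids = regulators)

  # -- substream 3: expression layer
  set.seed(cfg$seed + 2L)
  base <- stats::rnorm(cfg$n_expr_genes, 8, 2)
  names(base) <- expr_genes
  direction <- sample(c(-1, 1), cfg$n_signature, replace = TRUE)
  names(direction) <- sig_genes
  shift <- outer(direction / 2 * cfg$effect_size,
                 ifelse(short, 1, -1))  # signature genes x patients
  E <- matrix(stats::rnorm(cfg$n_expr_genes * n, 0, cfg$noise_sd),
              cfg$n_expr_genes, n, dimnames = list(expr_genes, patients))
  E <- E + base
  E[sig_genes, ] <- E[sig_genes, ] + shift
  # network targets: exact weighted sum of regulator expression plus noise
  E[targets, ] <- t(network$weights) %*% E[regulators, , drop = FALSE] +
    matrix(stats::rnorm(length(targets) * n, 0, cfg$noise_sd),
           length(targets), n)
  attr(E, "scale") <- "log2"

  # -- substream 4: miRNA layer
  set.seed(cfg$seed + 3L)
  mirnas <- sprintf("mir%04d", seq_len(cfg$n_mirnas))
  nonsig <- setdiff(expr_genes, sig_genes)
  hosts <- sample(nonsig, cfg$n_host_coupled)
  host_map <- setNames(rep(NA_character_, cfg$n_mirnas), mirnas)
  host_map[seq_len(cfg$n_host_coupled)] <- hosts
  mu_m <- stats::rnorm(cfg$n_mirnas, 4, 1)
  Mi <- matrix(stats::rnorm(cfg$n_mirnas * n, 0, cfg$noise_sd),
               cfg$n_mirnas, n, dimnames = list(mirnas, patients))
  Mi <- Mi + mu_m
  r <- cfg$host_coupling_r
  for (i in if (cfg$noise_sd > 0) seq_len(cfg$n_host_coupled) else integer()) {
    z_host <- (E[hosts[i], ] - base[hosts[i]]) / cfg$noise_sd
    z_ind <- (Mi[i, ] - mu_m[i]) / cfg$noise_sd
    Mi[i, ] <- mu_m[i] + cfg$noise_sd * (r * z_host + sqrt(1 - r^2) * z_ind)
  }

  # -- substream 5: survival
  surv <- survival_from_labels(labels, cfg$hazard_short, cfg$hazard_long,
                               cfg$censor_rate, seed = cfg$seed + 4L)

  # -- substream 6: miRNA missingness flags
  set.seed(cfg$seed + 5L)
  n_missing <- round(cfg$mirna_missing_fraction * n)
  mirna_missing <- setNames(rep(FALSE, n), patients)
  if (n_missing > 0)
    mirna_missing[sample.int(n, n_missing)] <- TRUE

  structure(list(mutations = M, expression = E, mirna = Mi,
                 mirna_missing = mirna_missing, survival = surv,
                 true_labels = labels, network = network,
                 host_map = host_map, config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic DNMT3A-mutant AML cohort\n")
  cat(sprintf("  %d patients (%d short-lived, %d long-lived), seed %d\n",
              x$config$n_patients, sum(x$true_labels == "short-lived"),
              sum(x$true_labels == "long-lived"), x$config$seed))
  cat(sprintf("  mutations: %d genes, mean %.1f mutated genes/patient\n",
              ncol(x$mutations), mean(rowSums(x$mutations))))
  cat(sprintf("  expression: %d genes (%d signature, %d planted links)\n",
              nrow(x$expression), x$config$n_signature,
              sum(x$network$weights != 0)))
  cat(sprintf("  miRNA: %d miRNAs, %d host-coupled, %d patients missing layer\n",
              nrow(x$mirna), x$config$n_host_coupled, sum(x$mirna_missing)))
  cat(sprintf("  survival: %d events, median follow-up %.0f days\n",
              sum(x$survival$event), stats::median(x$survival$time)))
  invisible(x)
}

#' Write all cohort layers to a directory
#'
#' Writes the standard TSV representation of each layer plus a ground-truth
#' JSON (labels and planted edge list).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mt <- data.frame(patient_id = rep(rownames(cohort$mutations),
                                    times = rowSums(cohort$mutations)),
                   gene = unlist(apply(cohort$mutations, 1, function(r)
                     colnames(cohort$mutations)[r == 1])),
                   stringsAsFactors = FALSE)
  write_mutation_table(as_mutation_table(mt), file.path(dir, "mutations.tsv"))
  write_expression_matrix(cohort$expression, file.path(dir, "expression.tsv"),
                          id_column = "gene")
  write_expression_matrix(cohort$mirna, file.path(dir, "mirna.tsv"),
                          id_column = "mirna")
  write_survival_table(cohort$survival, file.path(dir, "survival.tsv"))
  hm <- data.frame(mirna = names(cohort$host_map), host = cohort$host_map,
                   row.names = NULL)
  write.table(hm, file.path(dir, "host_map.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- list(labels = as.list(cohort$true_labels),
                mirna_missing = names(which(cohort$mirna_missing)),
                planted_edges = planted_edges(cohort$network))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
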