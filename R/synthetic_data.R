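#' Specification of a synthetic triple-negative cohort
#'
#' Defaults emulate the statistical structure of a 107-patient TN
#' microarray cohort with three latent molecular clusters at proportions
#' 22.4/44.9/32.7% (giving sizes 24/48/35 under largest-remainder
#' rounding): a luminal-AR axis up in cluster 1, a proliferation axis up
#' in clusters 2 and (less) 3, an immune axis up in cluster 3, M2-like
#' macrophage genes up in cluster 2 and M1-like genes up in cluster 3,
#' and a claudin-low-like subpopulation (26% of cluster 3) with low
#' epithelial-adhesion and high EMT expression. Event hazards are
#' cluster-specific with cluster 3 the most favourable; ages follow the
#' cluster means 64.6/56.8/51.9 years.
#'
#' @param n_samples Cohort size.
#' @param cluster_proportions Length-3 proportions summing to 1.
#' @param n_probes Total probe count of the array.
#' @param probes_per_gene Integer values a gene's probe count is drawn
#'   from (uniformly).
#' @param block_sizes Named gene counts for the signal blocks
#'   (luminal_ar, proliferation, immune, claudin, emt, m2, m1).
#' @param effect_size Log2 shift of an active block (default 1.5).
#' @param noise_sd Sample-level gene noise SD (default 0.7).
#' @param probe_noise_sd Probe-level noise SD around the gene value.
#' @param age_means,age_sd Per-cluster age distribution (years).
#' @param efs_hazards Per-cluster yearly event rates; cluster 3 lowest
#'   (default 0.10/0.10/0.04, a 0.4 hazard ratio for cluster 3).
#' @param censor_rate Yearly censoring rate (plus a 15-year cutoff).
#' @param claudin_low_fraction_in_c3 Fraction of cluster 3 that is
#'   claudin-low-like.
#' @param seed Integer seed; every generator draw is a deterministic
#'   function of the spec and this seed.
#' @return A validated `CohortSpec` list.
#' @export
cohort_spec <- function(n_samples = 107,
                        cluster_proportions = c(0.224, 0.449, 0.327),
                        n_probes = 4000,
                        probes_per_gene = 1:3,
                        block_sizes = c(luminal_ar = 60, proliferation = 80,
                                        immune = 70, claudin = 30, emt = 30,
                                        m2 = 30, m1 = 30),
                        effect_size = 1.5,
                        noise_sd = 0.7,
                        probe_noise_sd = 0.3,
                        age_means = c(64.6, 56.8, 51.9),
                        age_sd = 12,
                        efs_hazards = c(0.10, 0.10, 0.04),
                        censor_rate = 0.04,
                        claudin_low_fraction_in_c3 = 0.26,
                        seed = 1) {
  spec <- list(n_samples = as.integer(n_samples),
               cluster_proportions = cluster_proportions,
               n_probes = as.integer(n_probes),
               probes_per_gene = as.integer(probes_per_gene),
               block_sizes = block_sizes, effect_size = effect_size,
               noise_sd = noise_sd, probe_noise_sd = probe_noise_sd,
               age_means = age_means, age_sd = age_sd,
               efs_hazards = efs_hazards, censor_rate = censor_rate,
               claudin_low_fraction_in_c3 = claudin_low_fraction_in_c3,
               seed = as.integer(seed))
  required <- c("luminal_ar", "proliferation", "immune", "claudin", "emt",
                "m2", "m1")
  if (!all(required %in% names(spec$block_sizes))) {
    stop("block_sizes must name: ", paste(required, collapse = ", "))
  }
  if (abs(sum(spec$cluster_proportions) - 1) > 1e-8) {
    stop("cluster proportions must sum to 1")
  }
  if (length(spec$cluster_proportions) != 3) stop("three clusters expected")
  if (any(spec$efs_hazards <= 0)) stop("hazards must be > 0")
  ## each signal gene carries at least one probe
  if (sum(spec$block_sizes) > spec$n_probes) {
    stop("signal blocks exceed the probe budget")
  }
  class(spec) <- "CohortSpec"
  spec
}

immune_module_names <- c("HCK", "LCK", "IgG", "STAT1", "Interferon",
                         "MHC-I", "MHC-II")

## Gene symbols per block; immune genes are apportioned over the seven
## modules and named by module so module files can be emitted directly.
synthetic_gene_table <- function(block_sizes) {
  imm_sizes <- largest_remainder_sizes(block_sizes[["immune"]],
                                       rep(1 / 7, 7))
  imm <- unlist(lapply(seq_along(immune_module_names), function(i) {
    tag <- gsub("-", "", immune_module_names[i])
    sprintf("IMM_%s_%03d", tag, seq_len(imm_sizes[i]))
  }))
  list(
    luminal_ar = sprintf("LUM_%03d", seq_len(block_sizes[["luminal_ar"]])),
    proliferation = sprintf("PRO_%03d", seq_len(block_sizes[["proliferation"]])),
    immune = imm,
    claudin = sprintf("CLDN_%03d", seq_len(block_sizes[["claudin"]])),
    emt = sprintf("EMT_%03d", seq_len(block_sizes[["emt"]])),
    m2 = sprintf("MAC_M2_%03d", seq_len(block_sizes[["m2"]])),
    m1 = sprintf("MAC_M1_%03d", seq_len(block_sizes[["m1"]])),
    immune_modules = {
      tags <- gsub("-", "", immune_module_names)
      stats::setNames(lapply(seq_along(tags), function(i)
        sprintf("IMM_%s_%03d", tags[i], seq_len(imm_sizes[i]))),
        immune_module_names)
    })
}

## Expected log2 shift of each signal block in each cluster (columns) and
## the extra shifts carried by the claudin-low subpopulation.
block_shift_design <- function(e) {
  shifts <- rbind(luminal_ar    = c(e, 0, 0),
                  proliferation = c(0, e, e / 2),
                  immune        = c(0, 0, e),
                  claudin       = c(0, 0, 0),
                  emt           = c(0, 0, 0),
                  m2            = c(0, e, 0),
                  m1            = c(0, 0, e))
  colnames(shifts) <- paste0("C", 1:3)
  list(cluster = shifts,
       claudin_low = c(claudin = -e, emt = e))
}

## The array "platform" — gene list, probes per gene, baseline gene means —
## is a deterministic function of the spec alone (fixed internal seed), so
## that cohorts drawn with different seeds from the same spec share probes
## and baselines, as real cohorts profiled on the same chip do.
synthetic_platform <- function(spec) {
  tab <- synthetic_gene_table(spec$block_sizes)
  signal_genes <- c(tab$luminal_ar, tab$proliferation, tab$immune,
                    tab$claudin, tab$emt, tab$m2, tab$m1)
  block_of <- rep(c("luminal_ar", "proliferation", "immune", "claudin",
                    "emt", "m2", "m1"),
                  times = c(length(tab$luminal_ar), length(tab$proliferation),
                            length(tab$immune), length(tab$claudin),
                            length(tab$emt), length(tab$m2), length(tab$m1)))
  with_seed(20107L, {
    ## probes per gene: signal genes first, then null genes fill the budget
    ppg_signal <- sample(spec$probes_per_gene, length(signal_genes),
                         replace = TRUE)
    overflow <- sum(ppg_signal) - spec$n_probes
    while (overflow > 0) {              # trim multi-probe genes if over budget
      i <- which(ppg_signal > 1)[1L]
      ppg_signal[i] <- ppg_signal[i] - 1L
      overflow <- overflow - 1L
    }
    left <- spec$n_probes - sum(ppg_signal)
    ppg_null <- integer(0)
    while (sum(ppg_null) < left) {
      ppg_null <- c(ppg_null, sample(spec$probes_per_gene, 1L))
    }
    if (length(ppg_null)) {
      ppg_null[length(ppg_null)] <- ppg_null[length(ppg_null)] -
        (sum(ppg_null) - left)
      ppg_null <- ppg_null[ppg_null > 0]
    }
    genes <- c(signal_genes, sprintf("NULL_%04d", seq_along(ppg_null)))
    list(tab = tab, genes = genes,
         blocks_all = c(block_of, rep("null", length(ppg_null))),
         ppg = c(ppg_signal, ppg_null),
         mu = stats::rnorm(length(genes), 8, 1))
  })
}

#' Generate a synthetic triple-negative cohort
#'
#' Draws a probe-level expression matrix, probe annotation, planted
#' cluster labels, a clinical table (age, EFS/OS with cluster-dependent
#' exponential hazards and independent censoring), immune module
#' definitions and a per-cluster centroid matrix, all as a deterministic
#' function of the spec and its seed. The array "platform" (gene list,
#' probes per gene, baseline gene means) is drawn under a fixed internal
#' seed, so cohorts generated with different seeds share the same probes
#' and baselines, as real cohorts profiled on the same chip do.
#'
#' @param spec A [cohort_spec()].
#' @return List: `expression` (probe-level [expression_matrix()]),
#'   `annotation` ([probe_annotation()]), `truth` (integer cluster per
#'   sample), `claudin_low` (logical per sample), `clinical` (data.frame
#'   with sample_id, cluster, age, efs_time, efs_event, os_time,
#'   os_event), `modules` (the seven immune modules), `blocks` (all block
#'   gene lists), `centroids` (gene x cluster expected-profile matrix),
#'   `spec`.
#' @export
generate_tnbc_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "CohortSpec"))
  plat <- synthetic_platform(spec)
  tab <- plat$tab
  genes <- plat$genes
  blocks_all <- plat$blocks_all
  ppg <- plat$ppg
  mu <- plat$mu
  with_seed(spec$seed, {
    n <- spec$n_samples
    sizes <- largest_remainder_sizes(n, spec$cluster_proportions)
    cl <- rep(1:3, sizes)
    sample_ids <- sprintf("S%03d", seq_len(n))

    ## gene-level expression: baseline + cluster shift (+ claudin-low
    ## subpopulation shift) + sample noise
    design <- block_shift_design(spec$effect_size)
    shift <- matrix(0, length(genes), n)
    for (b in rownames(design$cluster)) {
      rows <- blocks_all == b
      shift[rows, ] <- rep(design$cluster[b, cl], each = sum(rows))
    }
    idx_c3 <- which(cl == 3)
    n_cl <- round(spec$claudin_low_fraction_in_c3 * length(idx_c3))
    claudin_low <- rep(FALSE, n)
    claudin_low[sample(idx_c3, n_cl)] <- TRUE
    for (b in names(design$claudin_low)) {
      rows <- blocks_all == b
      shift[rows, claudin_low] <- shift[rows, claudin_low] +
        design$claudin_low[[b]]
    }
    gene_values <- mu + shift +
      matrix(stats::rnorm(length(genes) * n, 0, spec$noise_sd),
             length(genes), n)

    ## probe-level propagation with probe noise
    gene_idx <- rep(seq_along(genes), times = ppg)
    probe_ids <- sprintf("%s_at%d", genes[gene_idx],
                         unlist(lapply(ppg, seq_len)))
    values <- gene_values[gene_idx, , drop = FALSE] +
      matrix(stats::rnorm(length(gene_idx) * n, 0, spec$probe_noise_sd),
             length(gene_idx), n)
    E <- expression_matrix(values, probe_ids = probe_ids,
                           sample_ids = sample_ids)
    ann <- probe_annotation(probe_ids, genes[gene_idx])

    ## clinical table: age, EFS and OS with cluster hazards
    age <- stats::rnorm(n, spec$age_means[cl], spec$age_sd)
    draw_surv <- function(hazards) {
      t_event <- stats::rexp(n, hazards[cl])
      t_cens <- pmin(stats::rexp(n, spec$censor_rate), 15)
      data.frame(time = pmin(t_event, t_cens),
                 event = as.integer(t_event <= t_cens))
    }
    efs <- draw_surv(spec$efs_hazards)
    os <- draw_surv(spec$efs_hazards * 0.8)
    clinical <- data.frame(sample_id = sample_ids, cluster = cl,
                           claudin_low = claudin_low, age = age,
                           efs_time = efs$time, efs_event = efs$event,
                           os_time = os$time, os_event = os$event,
                           stringsAsFactors = FALSE)

    ## expected (noise-free) gene-level centroid per cluster
    centroids <- mu + matrix(0, length(genes), 3)
    for (b in rownames(design$cluster)) {
      rows <- blocks_all == b
      centroids[rows, ] <- centroids[rows, ] +
        rep(design$cluster[b, ], each = sum(rows))
    }
    dimnames(centroids) <- list(genes, paste0("C", 1:3))

    list(expression = E, annotation = ann, truth = stats::setNames(cl, sample_ids),
         claudin_low = stats::setNames(claudin_low, sample_ids),
         clinical = clinical, modules = tab$immune_modules,
         blocks = tab[c("luminal_ar", "proliferation", "immune", "claudin",
                        "emt", "m2", "m1")],
         centroids = centroids[rownames(centroids) != "", , drop = FALSE],
         spec = spec)
  })
}

#' Specification of a synthetic two-class macrophage reference
#'
#' Emulates an M1/M2 polarized-macrophage expression reference: a
#' gene-level two-class matrix with planted differential genes of known
#' direction, used to exercise the SAM + signed-signature pipeline.
#'
#' @param n_per_class Samples per class (default 10).
#' @param n_genes Total genes.
#' @param n_de Planted differential genes.
#' @param de_effect Log2 shift of planted genes (default 3).
#' @param de_direction_split Fraction of planted genes up in M2.
#' @param noise_sd Noise SD (default 1, so `de_effect` is in sigma units).
#' @param seed Integer seed.
#' @return A validated `MacrophageSpec` list.
#' @export
macrophage_spec <- function(n_per_class = 10, n_genes = 400, n_de = 60,
                            de_effect = 3, de_direction_split = 0.5,
                            noise_sd = 1, seed = 1) {
  if (n_de > n_genes) stop("n_de exceeds n_genes")
  structure(list(n_per_class = as.integer(n_per_class),
                 n_genes = as.integer(n_genes), n_de = as.integer(n_de),
                 de_effect = de_effect,
                 de_direction_split = de_direction_split,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "MacrophageSpec")
}

#' Generate a synthetic M1/M2 macrophage reference
#'
#' Planted differential genes are named `MAC_M2_*` (up in M2) and
#' `MAC_M1_*` (up in M1) so that, by construction, they coincide with the
#' macrophage blocks of [generate_tnbc_cohort()] and a signature built
#' here can be scored on the cohort.
#'
#' @param spec A [macrophage_spec()].
#' @return List: `expression` (gene-level [expression_matrix()]),
#'   `annotation` (identity probe-to-gene map), `labels` (factor M1/M2
#'   per sample), `truth` (data.frame gene_symbol, direction in {+1,-1}
#'   for planted genes), `spec`.
#' @export
generate_macrophage_reference <- function(spec = macrophage_spec()) {
  stopifnot(inherits(spec, "MacrophageSpec"))
  with_seed(spec$seed, {
    n_up <- round(spec$de_direction_split * spec$n_de)  # up in M2
    n_dn <- spec$n_de - n_up
    genes <- c(sprintf("MAC_M2_%03d", seq_len(n_up)),
               sprintf("MAC_M1_%03d", seq_len(n_dn)),
               sprintf("MACNULL_%04d", seq_len(spec$n_genes - spec$n_de)))
    n <- 2L * spec$n_per_class
    labels <- factor(rep(c("M1", "M2"), each = spec$n_per_class),
                     levels = c("M1", "M2"))
    mu <- stats::rnorm(spec$n_genes, 8, 1)
    X <- mu + matrix(stats::rnorm(spec$n_genes * n, 0, spec$noise_sd),
                     spec$n_genes, n)
    is_m2 <- labels == "M2"
    if (n_up) X[seq_len(n_up), is_m2] <- X[seq_len(n_up), is_m2] + spec$de_effect
    if (n_dn) {
      rows <- n_up + seq_len(n_dn)
      X[rows, !is_m2] <- X[rows, !is_m2] + spec$de_effect
    }
    ids <- sprintf("M%02d", seq_len(n))
    E <- expression_matrix(X, probe_ids = genes, sample_ids = ids)
    truth <- data.frame(gene_symbol = genes[seq_len(spec$n_de)],
                        direction = c(rep(1, n_up), rep(-1, n_dn)),
                        stringsAsFactors = FALSE)
    list(expression = E, annotation = probe_annotation(genes, genes),
         labels = stats::setNames(labels, ids), truth = truth, spec = spec)
  })
}
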