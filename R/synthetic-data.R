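# Synthetic-data generators with known ground truth.
#
# Every downstream stage of the package is exercised on data from these
# generators: a plate-structured high-content screen with planted
# correlated knockdown modules, negative-binomial count matrices with
# known differentially expressed genes (module members sharing a DE
# signature), a time course with planted decay dynamics, and a small
# genome with promoter-enriched peaks and a matching coverage track.
# All generators are pure functions of (parameters, seed).

#' Ground truth for a synthetic high-content screen
#'
#' Modules are disjoint sets of knockdown names that share one latent
#' phenotype: each module has a latent feature-loading vector, and
#' every member's expected feature value is `effect_size` times that
#' loading. Independent Gaussian noise (`noise_sd`) is added per well
#' and feature, and an additive offset per (plate, feature) with SD
#' `plate_shift` plants the removable plate batch effect.
#'
#' @param modules list of character vectors (disjoint knockdown sets)
#' @param effect_size SD units of the shared latent signal (>= 0)
#' @param noise_sd per-feature residual SD (> 0)
#' @param plate_shift SD of the per-(plate, feature) additive offset
#' @return object of class `screen_truth`
#' @export
screen_truth <- function(modules = list(), effect_size = 2, noise_sd = 1,
                         plate_shift = 0.5) {
  modules <- lapply(modules, as.character)
  all_members <- unlist(modules)
  if (anyDuplicated(all_members))
    stop_config("module sets must be disjoint")
  if (effect_size < 0) stop_config("effect_size must be >= 0")
  if (noise_sd <= 0) stop_config("noise_sd must be > 0")
  if (plate_shift < 0) stop_config("plate_shift must be >= 0")
  structure(list(modules = modules, effect_size = effect_size,
                 noise_sd = noise_sd, plate_shift = plate_shift),
            class = "screen_truth")
}

#' Generate a plate-structured high-content screen table
#'
#' Produces one measured value per (knockdown, replicate, feature).
#' Replicate r is laid out on plate `((r - 1) mod n_plates) + 1`, so
#' each knockdown occupies one well per (plate, replicate). Module
#' members share a latent loading vector scaled by the truth's
#' `effect_size`; plate offsets are applied before any normalization so
#' that per-plate Z-scoring has a real batch effect to remove.
#'
#' @param n_knockdowns,n_features,n_replicates,n_plates design sizes;
#'   `n_replicates >= 2`, `n_features >= 1`
#' @param truth a [screen_truth()]; module members must be among the
#'   generated knockdown names `KD001 ...`
#' @param seed integer seed; identical seeds give identical tables
#' @return list with `table` (long-form screen data.frame) and `truth`
#'   (the input truth augmented with the drawn `loadings` and
#'   `plate_offsets`)
#' @export
generate_screen <- function(n_knockdowns, n_features, n_replicates,
                            n_plates = 2L, truth = screen_truth(),
                            seed = 1L) {
  if (n_features < 1) stop_config("n_features must be >= 1")
  if (n_replicates < 2) stop_config("n_replicates must be >= 2")
  if (n_plates < 1) stop_config("n_plates must be >= 1")
  knockdowns <- sprintf("KD%03d", seq_len(n_knockdowns))
  features <- sprintf("F%02d", seq_len(n_features))
  plates <- sprintf("P%d", seq_len(n_plates))
  unknown <- setdiff(unlist(truth$modules), knockdowns)
  if (length(unknown))
    stop_config("module member(s) not among knockdowns: %s",
                paste(unknown, collapse = ", "))
  with_seed(seed, {
    loadings <- lapply(truth$modules, function(m)
      stats::rnorm(n_features))
    plate_offsets <- matrix(stats::rnorm(n_plates * n_features,
                                         sd = truth$plate_shift),
                            n_plates, n_features,
                            dimnames = list(plates, features))
    base <- matrix(0, n_knockdowns, n_features,
                   dimnames = list(knockdowns, features))
    for (i in seq_along(truth$modules))
      base[truth$modules[[i]], ] <-
        rep(truth$effect_size * loadings[[i]], each = length(truth$modules[[i]]))
    plate_of_rep <- plates[(seq_len(n_replicates) - 1L) %% n_plates + 1L]
    rows <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      noise <- matrix(stats::rnorm(n_knockdowns * n_features,
                                   sd = truth$noise_sd),
                      n_knockdowns, n_features)
      vals <- base + noise +
        rep(plate_offsets[plate_of_rep[r], ], each = n_knockdowns)
      rows[[r]] <- data.frame(
        knockdown = rep(knockdowns, times = n_features),
        plate = plate_of_rep[r],
        replicate = r,
        feature = rep(features, each = n_knockdowns),
        value = as.vector(vals))
    }
    table <- do.call(rbind, rows)
    table <- table[order(table$knockdown, table$replicate, table$feature), ]
    rownames(table) <- NULL
    truth$loadings <- loadings
    truth$plate_offsets <- plate_offsets
    list(table = table, truth = truth)
  })
}

#' Ground truth for a synthetic negative-binomial expression study
#'
#' @param de_genes named list mapping each condition label to a named
#'   numeric vector `gene -> true log2 fold change vs baseline`;
#'   genes absent from a condition's vector have true log2FC = 0
#' @param dispersion NB dispersion alpha with `Var = mu + alpha mu^2`
#'   (0 degenerates to Poisson)
#' @param lib_sizes optional per-sample relative library sizes (> 0)
#' @param baseline_mu per-gene baseline means (> 0), recycled
#' @return object of class `expression_truth`
#' @export
expression_truth <- function(de_genes = list(), dispersion = 0.05,
                             lib_sizes = NULL, baseline_mu = 100) {
  if (dispersion < 0) stop_config("dispersion must be >= 0")
  if (!is.null(lib_sizes) && any(lib_sizes <= 0))
    stop_config("lib_sizes must be > 0")
  if (any(baseline_mu <= 0)) stop_config("baseline_mu must be > 0")
  structure(list(de_genes = de_genes, dispersion = dispersion,
                 lib_sizes = lib_sizes, baseline_mu = baseline_mu),
            class = "expression_truth")
}

#' Generate a negative-binomial count matrix with known DE genes
#'
#' Counts are drawn from NB with mean
#' `baseline_mu * 2^log2FC * lib-size scale` and dispersion alpha
#' (`Var = mu + alpha mu^2`); alpha = 0 gives Poisson draws.
#'
#' @param n_genes number of genes (`G0001 ...`)
#' @param groups character vector of condition labels, in order
#' @param reps_per_group replicates per condition (>= 2)
#' @param truth an [expression_truth()]
#' @param seed integer seed
#' @return list with `counts` (integer gene x sample matrix), `samples`
#'   (data.frame sample/group/replicate) and `truth`
#' @export
generate_expression_study <- function(n_genes, groups, reps_per_group,
                                      truth = expression_truth(),
                                      seed = 1L) {
  if (reps_per_group < 2) stop_config("reps_per_group must be >= 2")
  genes <- sprintf("G%04d", seq_len(n_genes))
  unknown <- setdiff(unlist(lapply(truth$de_genes, names)), genes)
  if (length(unknown))
    stop_config("de_genes refer to unknown gene(s): %s",
                paste(utils::head(unknown, 5), collapse = ", "))
  samples <- data.frame(
    sample = paste(rep(groups, each = reps_per_group),
                   seq_len(reps_per_group), sep = "_"),
    group = rep(groups, each = reps_per_group),
    replicate = rep(seq_len(reps_per_group), times = length(groups)))
  mu0 <- rep_len(truth$baseline_mu, n_genes)
  lib <- truth$lib_sizes %||% rep(1, nrow(samples))
  if (length(lib) != nrow(samples))
    stop_config("lib_sizes must have one entry per sample (%d)", nrow(samples))
  scale <- lib / mean(lib)
  with_seed(seed, {
    counts <- matrix(0L, n_genes, nrow(samples),
                     dimnames = list(genes, samples$sample))
    for (j in seq_len(nrow(samples))) {
      lfc <- rep(0, n_genes)
      de <- truth$de_genes[[samples$group[j]]]
      if (length(de)) lfc[match(names(de), genes)] <- de
      mu <- mu0 * 2^lfc * scale[j]
      counts[, j] <- if (truth$dispersion == 0) stats::rpois(n_genes, mu)
      else stats::rnbinom(n_genes, mu = mu, size = 1 / truth$dispersion)
    }
    list(counts = counts, samples = samples, truth = truth)
  })
}

#' Generate matched knockdown expression studies sharing module DE signatures
#'
#' Emulates a secondary RNA-seq screen over the knockdowns of a
#' high-content screen: each knockdown gets its own count study
#' (knockdown vs non-targeting control). Members of the same phenotype
#' module share one DE signature (identical true log2FCs on a common
#' gene subset) plus individual DE genes; unrelated knockdowns get
#' independent signatures, so transcriptome correlations recover the
#' modules.
#'
#' @param knockdowns character vector of knockdown names
#' @param modules list of disjoint knockdown subsets sharing signatures
#' @param n_genes genes per study
#' @param n_signature genes in each (shared or individual) signature
#' @param signature_sd SD of the true log2FCs drawn for signatures
#' @param reps_per_group,baseline_mu,dispersion passed to the NB model
#' @param seed integer seed
#' @return named list (per knockdown) of
#'   [generate_expression_study()] results; conditions are `"kd"` vs
#'   `"ctrl"`
#' @export
generate_knockdown_studies <- function(knockdowns, modules = list(),
                                       n_genes = 500, n_signature = 60,
                                       signature_sd = 1.5,
                                       reps_per_group = 3,
                                       baseline_mu = 100,
                                       dispersion = 0.05, seed = 1L) {
  genes <- sprintf("G%04d", seq_len(n_genes))
  with_seed(seed, {
    draw_sig <- function() {
      g <- sample(genes, n_signature)
      stats::setNames(stats::rnorm(n_signature, sd = signature_sd), g)
    }
    module_sig <- lapply(modules, function(m) draw_sig())
    study_seeds <- sample.int(.Machine$integer.max - 1L, length(knockdowns))
    out <- vector("list", length(knockdowns))
    names(out) <- knockdowns
    for (i in seq_along(knockdowns)) {
      kd <- knockdowns[i]
      in_mod <- which(vapply(modules, function(m) kd %in% m, logical(1)))
      sig <- if (length(in_mod)) module_sig[[in_mod[1]]] else draw_sig()
      tr <- expression_truth(de_genes = stats::setNames(list(sig), kd),
                             dispersion = dispersion,
                             baseline_mu = baseline_mu)
      out[[i]] <- generate_expression_study(
        n_genes, groups = c(kd, "ctrl"), reps_per_group = reps_per_group,
        truth = tr, seed = study_seeds[i])
    }
    out
  })
}

#' Generate a positive expression time course with planted dynamics
#'
#' Each gene set in `decay_sets` follows a relative expected-level
#' shape across timepoints (e.g. `c(1, 0.5, 0.25)` for decay, constant
#' for flat); genes are split evenly among the sets, any remainder
#' becoming flat background outside all sets. Per-gene baselines are
#' log-normal and noise is multiplicative, so all values stay > 0.
#'
#' @param n_genes number of genes
#' @param timepoints ordered character labels (>= 3)
#' @param decay_sets named list: set name -> positive numeric vector of
#'   relative expected levels, one per timepoint
#' @param noise_sd_log SD of the log-normal multiplicative noise
#' @param seed integer seed
#' @return matrix genes x timepoints with attribute `gene_sets`
#'   (named list of gene ids per set) and `shapes`
#' @export
generate_time_course <- function(n_genes, timepoints,
                                 decay_sets = list(decay = c(1, 0.5, 0.25),
                                                   flat = c(1, 1, 1)),
                                 noise_sd_log = 0.2, seed = 1L) {
  if (!length(timepoints)) stop_config("timepoints must be non-empty")
  if (length(timepoints) < 3) stop_config("need >= 3 timepoints")
  if (!length(decay_sets)) stop_config("decay_sets must be non-empty")
  bad <- vapply(decay_sets, function(s)
    length(s) != length(timepoints) || any(s <= 0), logical(1))
  if (any(bad))
    stop_config("each shape must be positive with one level per timepoint: %s",
                paste(names(decay_sets)[bad], collapse = ", "))
  genes <- sprintf("G%04d", seq_len(n_genes))
  n_per <- n_genes %/% length(decay_sets)
  if (n_per < 1) stop_config("fewer genes than decay sets")
  gene_sets <- split(genes[seq_len(n_per * length(decay_sets))],
                     rep(names(decay_sets), each = n_per))
  gene_sets <- gene_sets[names(decay_sets)]
  with_seed(seed, {
    baseline <- stats::rlnorm(n_genes, meanlog = log(100), sdlog = 1)
    expected <- matrix(1, n_genes, length(timepoints),
                       dimnames = list(genes, timepoints))
    for (nm in names(decay_sets))
      expected[gene_sets[[nm]], ] <- rep(decay_sets[[nm]],
                                         each = length(gene_sets[[nm]]))
    noise <- matrix(stats::rlnorm(length(expected), 0, noise_sd_log),
                    n_genes, length(timepoints))
    m <- baseline * expected * noise
    attr(m, "gene_sets") <- gene_sets
    attr(m, "shapes") <- decay_sets
    m
  })
}

#' Generate a gene annotation, promoter-enriched peaks and coverage
#'
#' Places `annotation_size` stranded genes uniformly on the given
#' chromosomes, then for each gene in `target_genes` plants, with
#' probability `frac_targeted`, a peak whose summit lies inside the
#' gene's promoter window (TSS +/- `flank`); `n_background_peaks`
#' additional peaks are placed uniformly on the genome. The coverage
#' track is built from simulated fixed-length reads with elevated
#' density under the peaks (see [coverage_from_reads()]), so signal
#' quantification recovers the peaks.
#'
#' @param annotation_size number of genes (`G0001 ...`)
#' @param chrom_sizes named numeric vector of chromosome lengths (bp)
#' @param target_genes subset of generated gene names to target
#' @param frac_targeted probability in `[0, 1]` that a target gene
#'   receives a promoter peak
#' @param flank half-width (bp, > 0) of the promoter window used for
#'   peak placement
#' @param n_background_peaks peaks placed uniformly outside any target
#' @param reads_per_peak,background_read_rate coverage read model:
#'   reads drawn around each summit, and background reads per bp
#' @param read_length simulated read length (bp)
#' @param seed integer seed
#' @return list with `genes` (GRanges, `name` column), `peaks`
#'   (GRanges with 0-based `summit` offset column), `coverage`
#'   ([coverage_track()]) and `target_genes`
#' @export
generate_genomic_tracks <- function(annotation_size, chrom_sizes,
                                    target_genes = character(),
                                    frac_targeted = 1, flank = 1000,
                                    n_background_peaks = 0,
                                    reads_per_peak = 50,
                                    background_read_rate = 2e-4,
                                    read_length = 50L, seed = 1L) {
  if (flank <= 0) stop_config("flank must be > 0")
  if (frac_targeted < 0 || frac_targeted > 1)
    stop_config("frac_targeted must be in [0, 1]")
  if (is.null(names(chrom_sizes)) || any(chrom_sizes <= 0))
    stop_config("chrom_sizes must be a named vector of positive lengths")
  gene_names <- sprintf("G%04d", seq_len(annotation_size))
  unknown <- setdiff(target_genes, gene_names)
  if (length(unknown))
    stop_config("target gene(s) not in annotation: %s",
                paste(unknown, collapse = ", "))
  chroms <- names(chrom_sizes)
  with_seed(seed, {
    gene_len <- 2000L
    # place genes in disjoint slots with a 2*flank margin so promoter
    # windows of distinct genes never overlap (and stay in bounds)
    slot <- gene_len + 4L * flank
    slots_per_chrom <- pmax(0L, floor(chrom_sizes / slot) - 1L)
    if (sum(slots_per_chrom) < annotation_size)
      stop_config("chromosomes too small for %d genes at flank %d",
                  annotation_size, flank)
    slot_chrom <- rep(chroms, slots_per_chrom)
    slot_idx <- unlist(lapply(slots_per_chrom, seq_len))
    pick <- sort(sample.int(length(slot_chrom), annotation_size))
    chrom <- slot_chrom[pick]
    start0 <- (slot_idx[pick] - 1L) * slot + 2L * flank +
      floor(stats::runif(annotation_size, 0, flank))
    strand <- sample(c("+", "-"), annotation_size, replace = TRUE)
    genes <- gintervals(chrom, start0, start0 + gene_len, strand = strand,
                        name = gene_names, seqlengths = chrom_sizes)
    genes <- GenomicRanges::sort(genes, ignore.strand = TRUE)

    tss0 <- ifelse(as.character(GenomicRanges::strand(genes)) == "+",
                   GenomicRanges::start(genes) - 1L,
                   GenomicRanges::end(genes))
    hit <- genes$name %in% target_genes &
      stats::runif(length(genes)) < frac_targeted
    peak_w <- 200L
    summit0 <- floor(tss0[hit] +
                       stats::runif(sum(hit), -flank, flank - 1))
    pk_chrom <- as.character(GenomicRanges::seqnames(genes))[hit]
    if (n_background_peaks > 0) {
      bg_chrom <- sample(chroms, n_background_peaks, replace = TRUE,
                         prob = chrom_sizes / sum(chrom_sizes))
      bg_summit <- vapply(bg_chrom, function(cn)
        floor(stats::runif(1, peak_w, chrom_sizes[[cn]] - peak_w)),
        numeric(1))
      pk_chrom <- c(pk_chrom, bg_chrom)
      summit0 <- c(summit0, bg_summit)
    }
    pk_start0 <- pmax(0, summit0 - peak_w %/% 2)
    pk_end0 <- pmin(chrom_sizes[pk_chrom], summit0 + peak_w %/% 2)
    peaks <- gintervals(pk_chrom, pk_start0, pk_end0,
                        name = sprintf("peak%03d", seq_along(pk_chrom)),
                        seqlengths = chrom_sizes)
    peaks$summit <- as.integer(summit0 - pk_start0)
    peaks <- GenomicRanges::sort(peaks, ignore.strand = TRUE)

    n_bg_reads <- stats::rpois(length(chroms), chrom_sizes * background_read_rate)
    read_chrom <- rep(chroms, n_bg_reads)
    read_start0 <- unlist(lapply(seq_along(chroms), function(i)
      floor(stats::runif(n_bg_reads[i], 0, chrom_sizes[i] - read_length))))
    pk_summit0 <- GenomicRanges::start(peaks) - 1L + peaks$summit
    for (i in seq_along(peaks)) {
      n <- stats::rpois(1, reads_per_peak)
      if (!n) next
      s0 <- floor(stats::rnorm(n, pk_summit0[i] - read_length / 2, 40))
      cn <- as.character(GenomicRanges::seqnames(peaks))[i]
      s0 <- pmin(pmax(s0, 0), chrom_sizes[[cn]] - read_length)
      read_chrom <- c(read_chrom, rep(cn, n))
      read_start0 <- c(read_start0, s0)
    }
    reads <- gintervals(read_chrom, read_start0, read_start0 + read_length,
                        seqlengths = chrom_sizes)
    list(genes = genes, peaks = peaks,
         coverage = coverage_from_reads(reads, read_length = read_length),
         target_genes = intersect(gene_names, target_genes))
  })
}
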