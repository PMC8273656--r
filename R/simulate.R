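#' Simulation configuration for matched tumor/normal read-depth profiles
#'
#' Describes the study conditions under which matched bin-count tables are
#' generated: a single synthetic chromosome carved into fixed-width bins, a
#' diploid normal sample, and a tumor sample diluted by purity with a set of
#' embedded copy-number variant regions.
#'
#' The defaults mirror a standard tumor simulation protocol: 22 variant
#' regions per sample (12 gains, 4 heterozygous losses at copy number 1,
#' 6 homozygous losses at copy number 0), lengths drawn from the six levels
#' 2, 6, 10, 30, 50 and 100 kb, sequencing coverage 10x with 100 bp reads,
#' and 2,000 bp bins. Gains draw copy numbers uniformly from 3..6.
#'
#' Bin counts are negative binomial around the GC-modulated expected depth;
#' `nb_size = Inf` gives the Poisson limit. The per-bin GC fraction follows a
#' smooth sinusoid in \[0.3, 0.6\] and depth responds quadratically to GC
#' (peaked near 0.45), so GC correction is exercised non-trivially.
#'
#' @param genome_length Chromosome length in bp.
#' @param bin_size Bin width in bp.
#' @param purity Tumor purity, fraction of tumor cells in (0, 1].
#' @param coverage Fold sequencing coverage.
#' @param read_length Read length in bp (sets reads-per-bin scale).
#' @param n_regions Number of embedded CNV regions.
#' @param gain_count,het_loss_count,hom_loss_count Composition of the regions;
#'   must sum to `n_regions`.
#' @param length_levels Candidate region lengths in bp (sampled uniformly).
#' @param length_range Permitted length range in bp; all `length_levels` must
#'   fall inside it.
#' @param gain_copy_numbers Integer copy numbers gains are drawn from.
#' @param nb_size Negative-binomial size (dispersion) parameter; `Inf` for
#'   Poisson counts.
#' @param chrom Chromosome name used in all output tables.
#' @return An object of class `cbcnv_sim_config` (a validated list).
#' @seealso [simulate_pair()], [plan_truth_regions()]
#' @export
sim_config <- function(genome_length = 4e7,
                       bin_size = 2000,
                       purity = 0.3,
                       coverage = 10,
                       read_length = 100,
                       n_regions = 22,
                       gain_count = 12,
                       het_loss_count = 4,
                       hom_loss_count = 6,
                       length_levels = c(2e3, 6e3, 1e4, 3e4, 5e4, 1e5),
                       length_range = c(2e3, 1e5),
                       gain_copy_numbers = 3:6,
                       nb_size = 100,
                       chrom = "chrS") {
  stopifnot_scalar_number(genome_length, "genome_length")
  stopifnot_scalar_number(bin_size, "bin_size")
  stopifnot_scalar_number(purity, "purity")
  if (purity <= 0 || purity > 1) stop("'purity' must be in (0, 1]", call. = FALSE)
  if (coverage <= 0) stop("'coverage' must be positive", call. = FALSE)
  if (gain_count + het_loss_count + hom_loss_count != n_regions) {
    stop("gain_count + het_loss_count + hom_loss_count must equal n_regions",
         call. = FALSE)
  }
  if (any(length_levels < length_range[1] | length_levels > length_range[2])) {
    stop("all 'length_levels' must lie within 'length_range'", call. = FALSE)
  }
  if (any(gain_copy_numbers <= 2)) {
    stop("'gain_copy_numbers' must all exceed the diploid 2", call. = FALSE)
  }
  cfg <- list(genome_length = genome_length, bin_size = bin_size,
              purity = purity, coverage = coverage, read_length = read_length,
              n_regions = as.integer(n_regions),
              gain_count = as.integer(gain_count),
              het_loss_count = as.integer(het_loss_count),
              hom_loss_count = as.integer(hom_loss_count),
              length_levels = length_levels, length_range = length_range,
              gain_copy_numbers = as.integer(gain_copy_numbers),
              nb_size = nb_size, chrom = chrom)
  class(cfg) <- "cbcnv_sim_config"
  cfg
}

#' Expected depth multiplier under the purity mixture model
#'
#' A sequenced tumor sample is a mixture of tumor cells (fraction `purity`,
#' local copy number `copy_number`) and normal cells (diploid). Relative to
#' the diploid baseline, expected read depth scales as
#' \deqn{(p \cdot c + (1-p) \cdot 2) / 2.}
#'
#' @param copy_number Non-negative integer copy number of the tumor cells.
#' @param purity Tumor purity in (0, 1].
#' @return The multiplicative depth factor (1 for diploid regions).
#' @examples
#' expected_depth_factor(2, 0.3)  # 1
#' expected_depth_factor(4, 0.3)  # 1.3
#' expected_depth_factor(0, 1.0)  # 0
#' @export
expected_depth_factor <- function(copy_number, purity) {
  if (any(copy_number < 0)) stop("'copy_number' must be >= 0", call. = FALSE)
  if (any(purity <= 0 | purity > 1)) stop("'purity' must be in (0, 1]", call. = FALSE)
  (purity * copy_number + (1 - purity) * 2) / 2
}

#' Place the ground-truth CNV regions for one simulated sample
#'
#' Draws `n_regions` disjoint, bin-aligned regions on the synthetic
#' chromosome with the configured gain/loss composition. Lengths are sampled
#' uniformly from `config$length_levels` and snapped to whole bins; regions
#' are separated by at least one diploid bin.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param max_tries Bounded retries for rejection placement before failing.
#' @return A data frame of truth regions with columns `chrom`, `start`,
#'   `end` (0-based half-open bp), `copy_number` and `type` ("gain"/"loss"),
#'   sorted by `start`.
#' @export
plan_truth_regions <- function(config, seed = NULL, max_tries = 1000L) {
  stopifnot(inherits(config, "cbcnv_sim_config"))
  n <- config$n_regions
  if (n == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), copy_number = integer(0),
                      type = character(0), stringsAsFactors = FALSE))
  }
  n_bins <- floor(config$genome_length / config$bin_size)
  with_seed(seed, {
    copy_numbers <- c(
      resample(config$gain_copy_numbers, config$gain_count, replace = TRUE),
      rep(1L, config$het_loss_count),
      rep(0L, config$hom_loss_count)
    )
    copy_numbers <- resample(copy_numbers, n)  # shuffle genomic order of types
    lens_bins <- pmax(1L, round(resample(config$length_levels, n, replace = TRUE) /
                                  config$bin_size))
    for (try in seq_len(max_tries)) {
      # place left-to-right with random gaps; guaranteed >= 1 bin separation
      need <- sum(lens_bins) + (n - 1L)      # bins consumed by regions + gaps
      slack <- n_bins - need
      if (slack < 1L) {
        stop("genome too short to place the requested regions", call. = FALSE)
      }
      cuts <- sort(sample.int(slack, n, replace = TRUE)) - 1L
      starts_bin <- cuts + c(0L, cumsum(lens_bins[-n] + 1L))
      ends_bin <- starts_bin + lens_bins
      if (all(ends_bin <= n_bins)) {
        out <- data.frame(
          chrom = config$chrom,
          start = starts_bin * config$bin_size,
          end = ends_bin * config$bin_size,
          copy_number = copy_numbers,
          type = ifelse(copy_numbers > 2L, "gain", "loss"),
          stringsAsFactors = FALSE
        )
        return(out[order(out$start), , drop = FALSE])
      }
    }
    stop("failed to place truth regions after bounded retries", call. = FALSE)
  })
}

# smooth per-bin GC fractions in [0.3, 0.6]
sim_gc_profile <- function(n_bins) {
  0.45 + 0.15 * sin(2 * pi * seq_len(n_bins) / 500)
}

# quadratic depth response to GC, peaked near 0.45, normalised to mean 1
sim_gc_response <- function(gc) {
  f <- 1.15 - 8 * (gc - 0.45)^2
  f / mean(f)
}

#' Simulate a matched tumor/normal bin-count pair with truth regions
#'
#' The normal sample draws per-bin counts around the diploid baseline
#' `lambda = coverage * bin_size / read_length`, modulated by the per-bin GC
#' response. The tumor sample uses the same GC modulation, times the purity
#' mixture factor [expected_depth_factor()] inside each truth region. Counts
#' are negative binomial with size `config$nb_size` (Poisson when `Inf`).
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; identical seeds reproduce identical output.
#' @return An object of class `cbcnv_sim`: a list with `tumor` and `normal`
#'   bin-count data frames (`chrom`, `bin_start`, `bin_end`, `count`),
#'   `truth` (see [plan_truth_regions()]), `gc` (per-bin GC fractions) and
#'   `config`.
#' @export
simulate_pair <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "cbcnv_sim_config"))
  n_bins <- floor(config$genome_length / config$bin_size)
  lambda <- config$coverage * config$bin_size / config$read_length
  with_seed(seed, {
    truth <- plan_truth_regions(config, seed = NULL)
    gc <- sim_gc_profile(n_bins)
    gc_mult <- sim_gc_response(gc)

    factor_t <- rep(1, n_bins)
    if (nrow(truth) > 0) {
      for (r in seq_len(nrow(truth))) {
        b0 <- truth$start[r] / config$bin_size + 1L
        b1 <- truth$end[r] / config$bin_size
        factor_t[b0:b1] <- expected_depth_factor(truth$copy_number[r],
                                                 config$purity)
      }
    }
    draw <- function(mu) {
      if (is.finite(config$nb_size)) {
        stats::rnbinom(n_bins, size = config$nb_size, mu = mu)
      } else {
        stats::rpois(n_bins, mu)
      }
    }
    starts <- (seq_len(n_bins) - 1L) * config$bin_size
    mk <- function(counts) data.frame(
      chrom = config$chrom, bin_start = starts,
      bin_end = starts + config$bin_size, count = counts,
      stringsAsFactors = FALSE
    )
    out <- list(
      tumor = mk(draw(lambda * gc_mult * factor_t)),
      normal = mk(draw(lambda * gc_mult)),
      truth = truth,
      gc = gc,
      config = config
    )
    class(out) <- "cbcnv_sim"
    out
  })
}

#' @export
print.cbcnv_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated tumor/normal pair: %d bins of %d bp, purity %.2f, coverage %gx\n",
    nrow(x$tumor), as.integer(x$config$bin_size), x$config$purity,
    x$config$coverage))
  cat(sprintf("  truth: %d regions (%d gain, %d loss)\n", nrow(x$truth),
              sum(x$truth$type == "gain"), sum(x$truth$type == "loss")))
  invisible(x)
}

#' Write a simulated pair to disk
#'
#' Emits `tumor.tsv` and `normal.tsv` (headered bin-count tables),
#' `truth.bed` (BED3+2: chrom, start, end, copy_number, type) and `gc.tsv`
#' (per-bin GC fractions) under `dir`.
#'
#' @param sim A `cbcnv_sim` object from [simulate_pair()].
#' @param dir Output directory, created if absent.
#' @return Invisibly, the paths written.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "cbcnv_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(tumor = file.path(dir, "tumor.tsv"),
             normal = file.path(dir, "normal.tsv"),
             truth = file.path(dir, "truth.bed"),
             gc = file.path(dir, "gc.tsv"))
  utils::write.table(sim$tumor, paths["tumor"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$normal, paths["normal"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_truth_bed(sim$truth, paths["truth"])
  utils::write.table(
    data.frame(chrom = sim$tumor$chrom, bin_start = sim$tumor$bin_start,
               bin_end = sim$tumor$bin_end, gc = sim$gc),
    paths["gc"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write truth regions as BED3+2
#' @param truth Truth data frame (see [plan_truth_regions()]).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_truth_bed <- function(truth, path) {
  utils::write.table(
    truth[, c("chrom", "start", "end", "copy_number", "type")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3+2 truth file written by [write_truth_bed()]
#' @param path BED file path.
#' @return Truth data frame with `chrom`, `start`, `end`, `copy_number`, `type`.
#' @export
read_truth_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "copy_number", "type")[seq_len(ncol(df))]
  df
}
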