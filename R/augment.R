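#' Noise standard deviation for a target signal-to-noise ratio
#'
#' For additive Gaussian noise `G' = G + N`, the SNR in decibels is
#' `10 * log10(P_signal / P_noise)`. Given a target SNR this returns the
#' noise standard deviation `sigma = sqrt(P_signal / 10^(snr_db/10))`.
#' Signal power defaults to the mean square of the (log-scale) profile
#' entries; `power = "variance"` uses the profile variance instead.
#'
#' @param profile Numeric vector, one sample's expression profile over the
#'   hub features.
#' @param snr_db Target signal-to-noise ratio in dB.
#' @param power Signal-power convention, `"mean_square"` (default) or
#'   `"variance"`.
#' @return Positive scalar sigma.
#' @export
#' @examples
#' noise_sigma(c(3, 4), snr_db = 10)  # P = 12.5, sigma = sqrt(1.25)
noise_sigma <- function(profile, snr_db,
                        power = c("mean_square", "variance")) {
  power <- match.arg(power)
  stopifnot(is.numeric(profile), length(profile) >= 1, is.finite(snr_db))
  p_signal <- switch(power,
    mean_square = mean(profile^2),
    variance = stats::var(profile)
  )
  if (!is.finite(p_signal) || p_signal <= 0) {
    stop("signal power is zero (all-zero or constant profile)", call. = FALSE)
  }
  sqrt(p_signal / 10^(snr_db / 10))
}

#' Augment a dataset with Gaussian-noise replicates at fixed SNR
#'
#' Expands a (hub-feature) dataset by adding, for each original sample,
#' `replicates` noisy copies `G' = G + N` where `N` is i.i.d. zero-mean
#' Gaussian with one per-sample sigma chosen so the signal-to-noise ratio
#' equals `snr_db` (see [noise_sigma()]). Replicates inherit their source
#' sample's labels; originals are preserved bit-exactly as replicate 0.
#'
#' @param ds An [expr_dataset], typically restricted to the selected hub
#'   genes.
#' @param snr_db Target SNR in dB (default 32: high-fidelity replicates
#'   that still explore each patient's neighbourhood).
#' @param replicates Noisy copies per original sample (default 3, so the
#'   61-patient cohort grows to a pool of 244).
#' @param seed Integer seed.
#' @param power Signal-power convention, see [noise_sigma()].
#' @return An `augmented_dataset` (an [expr_dataset] whose `samples` table
#'   gains `source_id`, `replicate` and `snr_db` columns).
#' @export
augment_dataset <- function(ds, snr_db = 32, replicates = 3, seed = 1,
                            power = c("mean_square", "variance")) {
  power <- match.arg(power)
  stopifnot(replicates >= 0)
  n <- ncol(ds$values)
  g <- nrow(ds$values)

  blocks <- list(ds$values)
  ann <- list(dplyr::mutate(ds$samples, source_id = .data$sample_id,
                            replicate = 0L, snr_db = snr_db))
  if (replicates > 0) {
    withr::with_seed(seed, {
      for (r in seq_len(replicates)) {
        noise <- matrix(stats::rnorm(g * n), nrow = g)
        sigmas <- apply(ds$values, 2, noise_sigma, snr_db = snr_db,
                        power = power)
        block <- ds$values + sweep(noise, 2, sigmas, `*`)
        colnames(block) <- paste0(colnames(ds$values), ".rep", r)
        blocks[[r + 1]] <- block
        ann[[r + 1]] <- dplyr::mutate(
          ds$samples,
          source_id = .data$sample_id,
          sample_id = paste0(.data$sample_id, ".rep", r),
          replicate = r, snr_db = snr_db
        )
      }
    })
  }
  out <- new_expr_dataset(
    do.call(cbind, blocks),
    dplyr::bind_rows(ann)[c("sample_id", "group", "depression",
                            "source_id", "replicate", "snr_db")],
    class = "augmented_dataset"
  )
  validate_expr_dataset(out)
}

#' Originals / replicates of an augmented dataset
#' @param aug An [augment_dataset()] result.
#' @return An [expr_dataset] with only the original (replicate 0) or only
#'   the replicated samples.
#' @export
originals <- function(aug) {
  subset_dataset(aug, samples = aug$samples$sample_id[aug$samples$replicate == 0])
}

#' @rdname originals
#' @export
replicates <- function(aug) {
  keep <- aug$samples$sample_id[aug$samples$replicate > 0]
  if (!length(keep)) stop("augmented dataset has no replicates", call. = FALSE)
  subset_dataset(aug, samples = keep)
}

#' Fidelity report for an augmented dataset
#'
#' Quality control for the noise model: the achieved SNR per source
#' sample, `10 * log10(P_signal / P_noise)` with the noise power estimated
#' from the replicate deviations, and the coordinates of originals and
#' replicates in the top-2 PCA plane of the combined pool (the visual
#' check that replicates cluster around their sources).
#'
#' @param aug An [augment_dataset()] result.
#' @param power Signal-power convention used at generation time.
#' @return A list of class `fidelity_report`: `snr` (tibble `source_id`,
#'   `achieved_snr_db`, `n_replicates`) and `projection` (tibble with
#'   `sample_id`, `source_id`, `replicate`, `PC1`, `PC2`).
#' @export
fidelity_report <- function(aug, power = c("mean_square", "variance")) {
  power <- match.arg(power)
  orig <- aug$samples$replicate == 0
  orig_ids <- aug$samples$sample_id[orig]

  snr <- purrr::map(orig_ids, function(id) {
    src <- aug$values[, id]
    reps <- aug$samples$sample_id[aug$samples$source_id == id &
                                    aug$samples$replicate > 0]
    if (!length(reps)) {
      return(tibble::tibble(source_id = id, achieved_snr_db = NA_real_,
                            n_replicates = 0L))
    }
    noise <- aug$values[, reps, drop = FALSE] - src
    p_signal <- switch(power, mean_square = mean(src^2),
                       variance = stats::var(src))
    tibble::tibble(
      source_id = id,
      achieved_snr_db = 10 * log10(p_signal / mean(noise^2)),
      n_replicates = length(reps)
    )
  }) |>
    dplyr::bind_rows()

  pc <- stats::prcomp(t(aug$values), center = TRUE, scale. = FALSE)
  projection <- tibble::tibble(
    sample_id = aug$samples$sample_id,
    source_id = aug$samples$source_id,
    replicate = aug$samples$replicate,
    PC1 = pc$x[, 1],
    PC2 = if (ncol(pc$x) >= 2) pc$x[, 2] else 0
  )
  structure(list(snr = snr, projection = projection),
            class = "fidelity_report")
}
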