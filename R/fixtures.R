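#' Generate the standard test fixture set
#'
#' Writes, deterministically for a given seed: a 128x128 three-class
#' phantom (`clean.png`) and its sigma = 0.2 speckled copy
#' (`noisy.png`); a 12x12 random image for brute-force oracle tests
#' (`oracle.tif`, 32-bit float so the round trip is lossless, small
#' enough for [naive_oracle_denoise]); and a 6-row Doppler CSV
#' (`doppler.csv`) spanning valid and invalid rows, including one
#' `edv > psv` artifact that [batch_ri] must flag.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Global seed; stage sub-seeds are derived by fixed
#'   offsets.
#' @return Character vector of the files written, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 0L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  seeds <- fan_seed(seed)

  clean <- make_phantom(phantom_spec(128L, 128L, c(0.2, 0.5, 0.8),
                                     seed = seeds$geometry))
  noisy <- add_speckle(clean, speckle_params(0.2, seed = seeds$noise))
  f_clean <- file.path(out_dir, "clean.png")
  f_noisy <- file.path(out_dir, "noisy.png")
  save_image(clean, f_clean)
  save_image(noisy, f_noisy)

  oracle <- with_seed(seeds$misc, matrix(runif(12 * 12), 12, 12))
  f_oracle <- file.path(out_dir, "oracle.tif")
  save_image(gray_image(oracle), f_oracle, bits = 32L)

  doppler <- data.frame(
    subject_id = sprintf("S%02d", 1:6),
    group = c("control", "control", "A", "A", "B", "B"),
    psv = c(100, 80, 110, 95, 100, 90),
    edv = c(42, 33.6, 35.2, 30.4, 37, 120))   # last row: edv > psv artifact
  f_csv <- file.path(out_dir, "doppler.csv")
  write.csv(doppler, f_csv, row.names = FALSE)

  invisible(c(f_clean, f_noisy, f_oracle, f_csv))
}
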