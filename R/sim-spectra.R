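#' Component basis spectra
#'
#' Full 421-channel basis vectors for the glucose (C6), xylose (C5),
#' S-lignin and G-lignin pyrolyzate components plus the broadband
#' background profile. Each component basis sums to 1, with 80% of its mass
#' on its diagnostic ions and 20% on the shared background (a decaying
#' profile over m/z 30-56); the background basis is the profile itself.
#'
#' @param config A [generator_config()].
#' @return A 421 x 5 matrix with columns `glucose`, `xylose`, `s_lignin`,
#'   `g_lignin`, `background`, rows in channel order m/z 30-450.
#' @export
component_basis <- function(config = generator_config()) {
  bg <- numeric(n_channels())
  i <- match(30:56, mz_channels())
  bg[i] <- exp(-(30:56 - 30) / 8)
  bg <- bg / sum(bg)
  one <- function(w) {
    stopifnot(!is.null(names(w)))
    mz <- as.integer(names(w))
    if (any(mz < MZ_MIN | mz > MZ_MAX)) {
      abort("basis channel outside m/z 30..450", class = "pymbms_error_config")
    }
    v <- numeric(n_channels())
    v[match(mz, mz_channels())] <- w / sum(w)
    0.8 * v + 0.2 * bg
  }
  b <- vapply(config$basis[c("glucose", "xylose", "s_lignin", "g_lignin")],
              one, numeric(n_channels()))
  cbind(b, background = bg)
}

# per-unit capture fractions of the labeled marker ions, used to solve the
# S/G intensity split
sg_capture <- function(basis) {
  lig <- lignin_ions()
  idx_s <- match(paste0("mz_", sg_members(lig, "S")), mz_cols())
  idx_g <- match(paste0("mz_", sg_members(lig, "G")), mz_cols())
  list(
    fS = sum(basis[idx_s, "s_lignin"]),
    fG = sum(basis[idx_g, "g_lignin"]),
    x150 = basis[match("mz_150", mz_cols()), "xylose"],
    idx_s = idx_s, idx_g = idx_g
  )
}

#' Compose synthetic py-MBMS spectra from latent compositions
#'
#' Each spectrum is the linear mixture `glucose * b_C6 + xylose * b_C5 +
#' S * b_S + G * b_G + other * b_bg`, where `other = 100 - glucose -
#' xylose - lignin` (so total pyrolyzate mass is constant across samples)
#' and the S/G intensity split of the lignin mass is solved per sample so
#' the S/G ion ratio of the noiseless spectrum equals the latent
#' `sg_ratio` exactly, accounting for the xylose contribution at m/z 150.
#' Channels are then multiplied by lognormal noise (mean 1) and the
#' spectrum is TIC normalized. Replicates get independent noise.
#' Deterministic given the seed.
#'
#' @param truth Output of [sample_compositions()] (or any tibble with the
#'   four trait columns and `sample_id`).
#' @param config A [generator_config()].
#' @param n_replicates Replicates per sample; defaults to the config value.
#' @param noise_sd Per-channel lognormal sigma; defaults to the config
#'   value. Set 0 for noiseless spectra.
#' @param seed Integer seed.
#' @return A TIC-normalized spectra table with `n * n_replicates` rows.
#' @export
compose_spectra <- function(truth, config = generator_config(),
                            n_replicates = config$n_replicates,
                            noise_sd = config$spectral_noise_sd, seed = 1) {
  basis <- component_basis(config)
  cap <- sg_capture(basis)
  n <- nrow(truth)
  glc <- truth$glucose_dw_pct
  xyl <- truth$xylose_dw_pct
  lig <- truth$lignin_pct
  sg <- truth$sg_ratio
  other <- 100 - glc - xyl - lig
  if (any(other < 0)) {
    abort("compositions exceed 100% dry weight", class = "pymbms_error_config")
  }
  # solve Sa*fS = sg * (Ga*fG + xyl*x150) with Sa + Ga = lignin
  Ga <- (lig * cap$fS - sg * xyl * cap$x150) / (cap$fS + sg * cap$fG)
  Ga <- pmax(Ga, 0)
  Sa <- lig - Ga
  A <- cbind(glc, xyl, Sa, Ga, other)  # abundances, samples x components
  clean <- A %*% t(basis)              # samples x channels
  p <- n_channels()
  rows <- withr::with_seed(seed, {
    lapply(seq_len(n_replicates), function(r) {
      noisy <- if (noise_sd > 0) {
        clean * exp(matrix(rnorm(n * p, 0, noise_sd), n, p) - noise_sd^2 / 2)
      } else {
        clean
      }
      noisy / rowSums(noisy)
    })
  })
  out <- bind_rows(lapply(seq_len(n_replicates), function(r) {
    m <- rows[[r]]
    colnames(m) <- mz_cols()
    bind_cols(
      tibble(sample_id = truth$sample_id, replicate_id = paste0("r", r)),
      as_tibble(m)
    )
  })) |>
    arrange(.data$sample_id, .data$replicate_id)
  new_spectra(out, "tic")
}

#' Noise-free standard spectra for single-point estimation
#'
#' Composes one noiseless spectrum per requested target at the generator's
#' mean composition and wraps each as a [reference_standard()] carrying the
#' corresponding latent mean as its known value, emulating a carefully
#' characterised reference material.
#'
#' @param config A [generator_config()].
#' @param targets Subset of `c("lignin", "glucose", "xylose")`.
#' @return Named list of [reference_standard()] objects.
#' @export
standards_from_config <- function(config = generator_config(),
                                  targets = c("lignin", "glucose", "xylose")) {
  targets <- match.arg(targets, several.ok = TRUE)
  truth <- tibble(
    sample_id = "standard",
    glucose_dw_pct = config$glucose$mean,
    xylose_dw_pct = config$xylose$mean,
    lignin_pct = config$lignin$mean,
    sg_ratio = config$sg$mean
  )
  sp <- compose_spectra(truth, config, n_replicates = 1, noise_sd = 0)
  known <- c(lignin = config$lignin$mean, glucose = config$glucose$mean,
             xylose = config$xylose$mean)
  setNames(
    lapply(targets, function(t) reference_standard(sp, known[[t]], t)),
    targets
  )
}
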