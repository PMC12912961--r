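# Two-channel lipid-domain image generator.
#
# Model: a square bilayer field carries circular lipid domains (disks with
# gamma-distributed areas, non-overlapping by rejection). The fluorescent
# lipid is uniformly distributed at density d0 in the "without lipopeptide"
# image; in the "with lipopeptide" image it is enriched E-fold inside the
# domains, with the out-of-domain density lowered so that the TOTAL number of
# fluorophores in the field is conserved. Inside the domains each molecule is
# self-quenched: its brightness is multiplied by a factor q in (0, 1]. The
# lipopeptide channel is nonzero only inside domains. No PSF, camera gain or
# drift is modeled.

#' Simulate a with/without-lipopeptide domain image pair
#'
#' @param image_params list as in [synthetic_config()]: `size_px`,
#'   `pixel_size_um`, `n_domains`, `mean_domain_area_um2`,
#'   `sd_domain_area_um2`, `density` (bulk fluorophores/pixel `d0`),
#'   `enrichment` (fold E >= 1), `quench` (q in (0, 1]), `noise_sd`,
#'   `background`.
#' @param seed integer seed.
#' @return a `domain_image_set`: list with `image_with` (list of matrices
#'   `pip2`, `peptide`), `image_without` (matrix `pip2`), `pixel_size_um`,
#'   `background`, and `truth` (enrichment fold, quench factor, logical
#'   domain `mask`, per-domain areas in µm², pre-quench density maps
#'   `density_with`, `density_without`).
#' @examples
#' img <- simulate_domain_images(list(size_px = 128, n_domains = 5), seed = 1)
#' sum(img$truth$density_with) - sum(img$truth$density_without)  # ~ 0
#' @export
simulate_domain_images <- function(image_params = list(), seed) {
  p <- modifyList(list(size_px = 256L, pixel_size_um = 0.16, n_domains = 25L,
                       mean_domain_area_um2 = 1.7, sd_domain_area_um2 = 0.2,
                       density = 50, enrichment = 3, quench = 0.75,
                       noise_sd = 0, background = 0), image_params)
  check_that(p$enrichment >= 1, "enrichment fold must be >= 1")
  check_that(p$quench > 0 && p$quench <= 1, "quench factor must lie in (0, 1]")
  S <- as.integer(p$size_px)
  px_area <- p$pixel_size_um^2
  field_area <- S^2 * px_area

  withr::with_seed(substream_seed(seed, "domains"), {
    # gamma-distributed domain areas with the requested mean and SD
    shape <- (p$mean_domain_area_um2 / p$sd_domain_area_um2)^2
    rate  <- p$mean_domain_area_um2 / p$sd_domain_area_um2^2
    areas <- rgamma(p$n_domains, shape = shape, rate = rate)
    check_that(sum(areas) < 0.5 * field_area,
               "total domain area must be well below the field area")
    radii_px <- sqrt(areas / pi) / p$pixel_size_um
    # non-overlapping disk centers by rejection sampling
    centers <- matrix(NA_real_, p$n_domains, 2)
    for (i in seq_len(p$n_domains)) {
      placed <- FALSE
      for (try in seq_len(5000L)) {
        xy <- runif(2, min = radii_px[i] + 2, max = S - radii_px[i] - 1)
        if (i == 1 ||
            all(sqrt(rowSums((centers[seq_len(i - 1), , drop = FALSE] -
                              matrix(xy, i - 1, 2, byrow = TRUE))^2)) >
                radii_px[i] + radii_px[seq_len(i - 1)] + 2)) {
          centers[i, ] <- xy; placed <- TRUE; break
        }
      }
      check_that(placed, "could not place %d non-overlapping domains", p$n_domains)
    }
    noise_w  <- if (p$noise_sd > 0) matrix(rnorm(S * S, 0, p$noise_sd), S, S) else 0
    noise_wo <- if (p$noise_sd > 0) matrix(rnorm(S * S, 0, p$noise_sd), S, S) else 0
    noise_pep <- if (p$noise_sd > 0) matrix(rnorm(S * S, 0, p$noise_sd), S, S) else 0
  })

  xg <- matrix(rep(seq_len(S), S), S, S)
  yg <- t(xg)
  mask <- matrix(FALSE, S, S)
  for (i in seq_len(p$n_domains)) {
    mask <- mask | ((xg - centers[i, 1])^2 + (yg - centers[i, 2])^2 <=
                      radii_px[i]^2)
  }
  n_dom_px <- sum(mask)

  # molecule-count conservation: enriched domains drain the bulk
  d0 <- p$density
  density_without <- matrix(d0, S, S)
  d_out <- d0 * (S^2 - p$enrichment * n_dom_px) / (S^2 - n_dom_px)
  check_that(d_out >= 0,
             "enrichment x domain area exceeds the total fluorophore pool")
  density_with <- matrix(d_out, S, S)
  density_with[mask] <- p$enrichment * d0

  bright_with <- density_with
  bright_with[mask] <- bright_with[mask] * p$quench   # self-quenching in domains

  pip2_with    <- bright_with + p$background + noise_w
  pip2_without <- density_without + p$background + noise_wo
  peptide <- matrix(0, S, S)
  peptide[mask] <- d0 * p$enrichment                   # arbitrary bright level
  peptide <- peptide + p$background + noise_pep

  structure(
    list(image_with = list(pip2 = pip2_with, peptide = peptide),
         image_without = list(pip2 = pip2_without),
         pixel_size_um = p$pixel_size_um,
         background = p$background,
         truth = list(enrichment = p$enrichment, quench = p$quench,
                      mask = mask, areas_um2 = pi * (radii_px * p$pixel_size_um)^2,
                      density_with = density_with,
                      density_without = density_without)),
    class = "domain_image_set")
}

#' @export
print.domain_image_set <- function(x, ...) {
  S <- nrow(x$image_with$pip2)
  cat(sprintf("Domain image pair: %dx%d px at %.3g um/px", S, S, x$pixel_size_um))
  if (!is.null(x$truth))
    cat(sprintf(" | truth: E = %.3g, q = %.3g, %d domains",
                x$truth$enrichment, x$truth$quench, length(x$truth$areas_um2)))
  cat("\n")
  invisible(x)
}

#' Write / read a domain image set as multi-channel TIFF + JSON sidecar
#'
#' Channels are written as a 3-slice float TIFF (with-lipopeptide PI(4,5)P2,
#' lipopeptide, without-lipopeptide PI(4,5)P2), linearly scaled to [0, 1];
#' the scale factor, channel order and pixel size live in `<path>.json`.
#'
#' @param images a `domain_image_set`.
#' @param path TIFF file path.
#' @return `read_domain_images()` returns a `domain_image_set` (without the
#'   synthetic truth block).
#' @export
write_domain_images <- function(images, path) {
  ch <- list(images$image_with$pip2, images$image_with$peptide,
             images$image_without$pip2)
  scale <- max(1, vapply(ch, max, numeric(1)))
  tiff::writeTIFF(lapply(ch, function(m) pmax(m, 0) / scale), path,
                  bits.per.sample = 32L)
  jsonlite::write_json(
    list(channels = c("pip2_with", "peptide", "pip2_without"),
         scale = scale, pixel_size_um = images$pixel_size_um,
         background = images$background / scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_domain_images
#' @export
read_domain_images <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ch <- tiff::readTIFF(path, all = TRUE)
  ch <- lapply(ch, function(m) m * meta$scale)
  names(ch) <- meta$channels
  structure(
    list(image_with = list(pip2 = ch$pip2_with, peptide = ch$peptide),
         image_without = list(pip2 = ch$pip2_without),
         pixel_size_um = meta$pixel_size_um,
         background = meta$background * meta$scale,
         truth = NULL),
    class = "domain_image_set")
}
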