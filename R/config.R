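#' Default simulation configuration
#'
#' Builds the nested configuration list consumed by [run_pipeline()] and the
#' individual stage functions. Defaults describe the desk-scale study
#' conditions: a 27 Mb genome in 12 chromosomes carrying tandem and dispersed
#' repeat families, a 10-plate (3,840-clone) BAC library with 50 kb mean
#' inserts and 20% empty wells (5.7 genome equivalents), five-enzyme HICF
#' fingerprinting with 0.15 nt sizing noise, and a 215-marker panel of which
#' 20% amplify duplicated loci.
#'
#' @param seed integer seed controlling every stochastic stage.
#' @param ... named overrides, e.g. `genome = list(genome_bp = 2e6)`; each
#'   override replaces the matching entry of the corresponding section.
#' @return A named list with sections `genome`, `library`, `fingerprint`,
#'   `assembly`, `screening`, `markers` plus the `seed`, of class
#'   `"sim_config"`.
#' @examples
#' cfg <- sim_config(seed = 1, genome = list(genome_bp = 2e6, n_chromosomes = 2))
#' cfg$genome$genome_bp
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    genome = list(
      genome_bp      = 27e6,
      n_chromosomes  = 12L,
      cm_per_mb      = 2.7,
      tandem   = list(n_families = 2L, unit_bp = 5000L, n_copies = 30L,
                      divergence = 0.01),
      dispersed = list(n_families = 2L, unit_bp = 3000L, n_copies = 25L,
                       divergence = 0.02)
    ),
    library = list(
      plates         = 10L,
      insert_mean_bp = 50e3,
      insert_sd_bp   = 5e3,
      empty_fraction = 0.2
    ),
    fingerprint = list(
      sizing_sd_nt = 0.15,
      fail_rate    = 0.2
    ),
    markers = list(
      n            = 215L,
      dup_fraction = 0.2,
      class_counts = c(RFLP = 117L, SNP = 96L, SSR = 2L)
    ),
    screening = list(
      fn_rate        = 0,
      fp_rate        = 0,
      superpool_size = 5L
    )
  )
  cfg$fingerprint$params <- band_calling_params()
  cfg$assembly <- assembly_params()
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("unknown config section: ", nm)
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(dots[[nm]])) cfg[[nm]][[k]] <- dots[[nm]][[k]]
    } else cfg[[nm]] <- dots[[nm]]
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Read or write a run configuration as YAML
#'
#' The serialized copy is the record of a run's conditions; [run_pipeline()]
#' writes one into every output directory.
#'
#' @param path file path.
#' @param config a [sim_config()] list.
#' @return `read_config()` returns the configuration list; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- sim_config(seed = raw$seed %||% 1L)
  for (nm in setdiff(names(raw), "seed")) {
    if (!nm %in% names(cfg)) stop("unknown config section in file: ", nm)
    if (is.list(raw[[nm]])) {
      for (k in names(raw[[nm]])) cfg[[nm]][[k]] <- raw[[nm]][[k]]
    } else cfg[[nm]] <- raw[[nm]]
  }
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Fixed rounding rule used for every reported percentage and average
#' (`round()` in R rounds half to even, which does not reproduce printed
#' summary tables).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(14.667)  # 15
#' round_half_up(4.392, 1)
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# derive a reproducible sub-seed for a pipeline stage, kept within 32-bit range
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 113 + offset) %% .Machine$integer.max)
}
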