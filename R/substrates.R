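# Substrate library: hybrid construct geometry and calibrated kinetic presets.
#
# Constructs are length-parametrized; no nucleotide sequences are modelled
# because none of the analysed quantities depend on base identity.  The
# shipped library lives in inst/extdata/substrates.yaml; users may load their
# own config with read_substrate_config().

.hk <- new.env(parent = emptyenv())

SEGMENT_KINDS <- c("ssDNA_overhang_3p", "ssDNA_overhang_5p",
                   "ssRNA_overhang_5p", "rna_dna_hybrid", "dsDNA")
JUNCTION_TYPES <- c("CJ", "NJ3p", "NJ5p", "OJ3p", "OJ5p", "BE", "inner")

#' Path of the bundled substrate configuration file
#' @return Character path to the YAML library shipped with the package.
#' @export
substrate_config_path <- function() {
  system.file("extdata", "substrates.yaml", package = "hybridkin",
              mustWork = TRUE)
}

#' Read a substrate configuration file
#'
#' Parses a YAML substrate library (the bundled one or a user-supplied file)
#' into a list of validated `substrate_spec` objects plus their raw preset
#' blocks.
#'
#' @param path Path to a YAML config (default: the bundled library).
#' @return A list with elements `config_version`, `defaults` and `substrates`
#'   (named list of `substrate_spec`).
#' @export
read_substrate_config <- function(path = substrate_config_path()) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$substrates)) {
    stop("substrate config has no 'substrates' entry: ", path)
  }
  subs <- lapply(raw$substrates, as_substrate_spec)
  names(subs) <- vapply(subs, function(s) s$name, character(1))
  if (anyDuplicated(names(subs))) {
    stop("duplicated substrate names in config: ",
         paste(unique(names(subs)[duplicated(names(subs))]), collapse = ", "))
  }
  list(config_version = raw$config_version,
       defaults = raw$defaults,
       substrates = subs)
}

as_substrate_spec <- function(x) {
  seg <- do.call(rbind, lapply(x$segments, function(s) {
    data.frame(kind = s$kind, length = as.numeric(s$length))
  }))
  jun <- do.call(rbind, lapply(x$junctions, function(j) {
    data.frame(type = j$type, position = as.numeric(j$position))
  }))
  spec <- structure(
    list(name = x$name,
         description = x$description %||% "",
         segments = seg,
         junctions = jun,
         labels = x$labels,
         preset_config = x$preset),
    class = "substrate_spec")
  validate_substrate(spec)
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a substrate specification
#'
#' Checks segment kinds and lengths, that junctions sit at segment boundaries
#' (the `inner` junction marks the hybrid midspan instead), that junction
#' types are consistent with the segment layout (e.g. an `OJ3p` junction
#' exists iff a 3' ssDNA overhang abuts the hybrid) and that hybrids carry at
#' least one junction.
#'
#' @param spec A `substrate_spec`.
#' @return The spec, invisibly; errors on violation.
#' @export
validate_substrate <- function(spec) {
  seg <- spec$segments
  jun <- spec$junctions
  if (!all(seg$kind %in% SEGMENT_KINDS)) {
    stop("unknown segment kind in '", spec$name, "': ",
         paste(setdiff(seg$kind, SEGMENT_KINDS), collapse = ", "))
  }
  if (any(seg$length <= 0)) stop("segment lengths must be > 0 in ", spec$name)
  if (!all(jun$type %in% JUNCTION_TYPES)) {
    stop("unknown junction type in '", spec$name, "': ",
         paste(setdiff(jun$type, JUNCTION_TYPES), collapse = ", "))
  }
  bounds <- c(0, cumsum(seg$length))
  not_inner <- jun$type != "inner"
  if (!all(jun$position[not_inner] %in% bounds)) {
    stop("junction positions must lie at segment boundaries in ", spec$name)
  }
  # hybrid constructs must carry at least one junction
  if (any(seg$kind == "rna_dna_hybrid") && nrow(jun) == 0) {
    stop("hybrid construct '", spec$name, "' has no junction")
  }
  # junction/segment consistency
  hyb <- which(seg$kind == "rna_dna_hybrid")
  for (i in seq_len(nrow(jun))) {
    type <- jun$type[i]; pos <- jun$position[i]
    ok <- switch(type,
      OJ3p = any(vapply(hyb, function(h) {
        h > 1 && seg$kind[h - 1] == "ssDNA_overhang_3p" &&
          bounds[h] == pos
      }, logical(1))),
      OJ5p = any(vapply(hyb, function(h) {
        (h > 1 && seg$kind[h - 1] %in%
           c("ssDNA_overhang_5p", "ssRNA_overhang_5p") && bounds[h] == pos) ||
        (h < nrow(seg) && seg$kind[h + 1] %in%
           c("ssDNA_overhang_5p", "ssRNA_overhang_5p") && bounds[h + 1] == pos)
      }, logical(1))),
      CJ = ,
      NJ3p = ,
      NJ5p = any(vapply(hyb, function(h) {
        (h > 1 && seg$kind[h - 1] == "dsDNA" && bounds[h] == pos) ||
        (h < nrow(seg) && seg$kind[h + 1] == "dsDNA" && bounds[h + 1] == pos)
      }, logical(1))),
      BE = any(vapply(hyb, function(h) {
        (h == 1 && pos == 0) || (h == nrow(seg) && pos == bounds[h + 1])
      }, logical(1))),
      inner = any(vapply(hyb, function(h) {
        pos > bounds[h] && pos < bounds[h + 1]
      }, logical(1))))
    if (!isTRUE(ok)) {
      stop("junction ", type, " at position ", pos,
           " is inconsistent with the segment layout of ", spec$name)
    }
  }
  invisible(spec)
}

library_cache <- function() {
  if (is.null(.hk$library)) .hk$library <- read_substrate_config()
  .hk$library
}

normalize_substrate_name <- function(name) {
  # strip prime/apostrophe marks so 3'ORDH, 3′ORDH and 3ORDH all match
  x <- gsub("[′’']", "", name)
  x <- toupper(trimws(x))
  if (x == "3ORDH25") x <- "3ORDH"
  x
}

lookup_substrate <- function(name, config = NULL) {
  lib <- if (is.null(config)) library_cache() else config
  keys <- vapply(names(lib$substrates), normalize_substrate_name, character(1))
  hit <- which(keys == normalize_substrate_name(name))
  if (length(hit) != 1) {
    stop("unknown substrate '", name, "'; valid entries: ",
         paste(names(lib$substrates), collapse = ", "))
  }
  lib$substrates[[hit]]
}

#' Look up a substrate construct
#'
#' @param name Substrate identifier (e.g. `"3ORDH"`, `"D/R/DH"`, `"D:R"`).
#'   Prime characters are ignored, so `"3'ORDH"` works too.
#' @param config Optional config list from [read_substrate_config()]; default
#'   is the bundled library.
#' @return A `substrate_spec` with `segments`, `junctions` and `labels`.
#' @examples
#' s <- get_substrate("3ORDH")
#' s$segments
#' @export
get_substrate <- function(name, config = NULL) {
  lookup_substrate(name, config)
}

#' List the substrates available in a library
#' @inheritParams get_substrate
#' @return Character vector of substrate names.
#' @export
list_substrates <- function(config = NULL) {
  lib <- if (is.null(config)) library_cache() else config
  names(lib$substrates)
}

#' Build the calibrated kinetic preset for a substrate
#'
#' Solves the calibration equations that pin per-site rate constants to the
#' dissociation-constant targets of the library.  The dwell-time estimator
#' used throughout the package is Kd = tau_unbound / (tau_bound x C), so for
#' a site with target Kd at calibration concentration C the mean unbound
#' waiting time to that site is tau_u = Kd x tau_b x C, giving
#' k_on = 1 / (tau_u x C) and k_off = 1 / tau_b.
#'
#' One free parameter remains per site (the bound dwell).  Unless the library
#' pins it (the 5'ORDH entry pins the measured 0.23 s / 6.56 s dwells), the
#' bound dwell is chosen as `tau_b = max(2, 4 * frame_interval / (Kd * C))`
#' seconds so that both the bound and the unbound dwell average at least four
#' camera frames and are resolvable by idealization.
#'
#' For dual-site competition presets carrying an `event_ratio` block, the
#' binding-event ratio is enforced through the on-rate ratio and the two
#' bound dwells are solved jointly so that both sites still meet their Kd
#' targets.  A `diffusion` block with `hop_fraction` h solves for the
#' bound-state hop rate k_diff such that a fraction h of binding episodes
#' contains at least one inter-site hop before release.
#'
#' @inheritParams get_substrate
#' @return A `kinetic_preset` with a per-site rate table (`sites`), the hop
#'   rate `k_diff`, the `cleavage` parameters, FRET anchors for degradation
#'   rendering and the calibration concentration.
#' @examples
#' p <- get_preset("3ORDH")
#' p$sites
#' @export
get_preset <- function(name, config = NULL) {
  spec <- lookup_substrate(name, config)
  pc <- spec$preset_config
  if (is.null(pc)) stop("substrate '", spec$name, "' has no preset block")
  C <- as.numeric(pc$calibration_concentration)
  frame <- as.numeric(pc$frame_interval %||% 0.5)

  sites <- do.call(rbind, lapply(pc$sites, function(s) {
    data.frame(site = s$site,
               E_bound = as.numeric(s$E_bound),
               kd_target = as.numeric(s$kd_target %||% NA_real_),
               tau_bound = as.numeric(s$tau_bound %||% NA_real_),
               tau_unbound = as.numeric(s$tau_unbound %||% NA_real_))
  }))

  # resolve pinned dwells: a pinned (tau_bound, tau_unbound) pair defines the
  # Kd target through the printed formula itself
  for (i in seq_len(nrow(sites))) {
    if (is.na(sites$kd_target[i])) {
      if (is.na(sites$tau_bound[i]) || is.na(sites$tau_unbound[i])) {
        stop("site ", sites$site[i], " of ", spec$name,
             " needs either kd_target or pinned dwell times")
      }
      sites$kd_target[i] <-
        sites$tau_unbound[i] / (sites$tau_bound[i] * C)
    }
  }

  er <- pc$event_ratio
  if (!is.null(er)) {
    # joint solution: k_on ratio fixed by the event-count ratio, bound dwells
    # adjusted per site so both Kd targets hold
    ia <- match(er$sites[[1]], sites$site)
    ib <- match(er$sites[[2]], sites$site)
    ratio <- as.numeric(er$counts[[1]]) / as.numeric(er$counts[[2]])
    kd_a <- sites$kd_target[ia]; kd_b <- sites$kd_target[ib]
    tb_a <- max(2, 4 * frame / (kd_a * C))
    tb_b <- ratio * (kd_a / kd_b) * tb_a
    sites$tau_bound[ia] <- tb_a
    sites$tau_bound[ib] <- tb_b
  }

  pinned <- !is.na(sites$tau_unbound)
  for (i in seq_len(nrow(sites))) {
    if (is.na(sites$tau_bound[i])) {
      sites$tau_bound[i] <- max(2, 4 * frame / (sites$kd_target[i] * C))
    }
    if (is.na(sites$tau_unbound[i])) {
      sites$tau_unbound[i] <-
        sites$kd_target[i] * sites$tau_bound[i] * C
    }
  }
  if (!any(pinned)) {
    # resolvability: the aggregate unbound waiting time over all competing
    # sites must average >= 40 frames, so that only ~1% of unbound
    # gaps fall below one frame and event counting stays reliable; scaling
    # every bound dwell by a common factor preserves all Kd targets and
    # on-rate ratios
    tu_total <- 1 / sum(1 / sites$tau_unbound)
    if (tu_total < 40 * frame) {
      fac <- 40 * frame / tu_total
      sites$tau_bound <- sites$tau_bound * fac
      sites$tau_unbound <- sites$tau_unbound * fac
    }
  }
  sites$k_off <- 1 / sites$tau_bound
  sites$k_on <- 1 / (sites$tau_unbound * C)
  if (any(!is.finite(sites$k_on)) || any(sites$k_on <= 0) ||
      any(!is.finite(sites$k_off)) || any(sites$k_off <= 0)) {
    stop("infeasible calibration for ", spec$name,
         ": non-positive rate constant")
  }

  k_diff <- 0
  if (!is.null(pc$diffusion) && nrow(sites) >= 2) {
    h <- as.numeric(pc$diffusion$hop_fraction)
    pi_i <- sites$k_on / sum(sites$k_on)
    f <- function(kd) sum(pi_i * kd / (kd + sites$k_off)) - h
    k_diff <- stats::uniroot(f, c(1e-12, 1e6), tol = 1e-14)$root
  }

  cl <- pc$cleavage %||% list(mode = "distributive")
  cleavage <- list(mode = cl$mode,
                   k_step = as.numeric(cl$k_step %||% 10),
                   k_cut = as.numeric(cl$k_cut %||% 100),
                   k_release = as.numeric(cl$k_release %||% 0.001),
                   cut_size = as.numeric(cl$cut_size %||% 4),
                   min_rna = as.numeric(cl$min_rna %||% 4))

  preset <- structure(
    list(substrate = spec$name,
         sites = sites,
         k_diff = k_diff,
         cleavage = cleavage,
         rna_length = as.numeric(pc$rna_length),
         E_degraded_start = as.numeric(pc$E_degraded_start %||% 0.2),
         E_degraded_end = as.numeric(pc$E_degraded_end %||% 0.7),
         baseline_E = 0.05,
         calibration_concentration = C,
         frame_interval = frame),
    class = "kinetic_preset")
  validate_preset(preset)
  preset
}

#' Check calibration closure of a kinetic preset
#'
#' Verifies that applying the dwell-time Kd formula to the analytic mean
#' dwells implied by the preset's rates, at the calibration concentration,
#' reproduces every site's target dissociation constant to within `tol`
#' relative error, and that all rates and FRET anchors are admissible.
#'
#' @param preset A `kinetic_preset`.
#' @param tol Maximum relative closure error (default `1e-9`).
#' @return The preset, invisibly; errors on violation.
#' @export
validate_preset <- function(preset, tol = 1e-9) {
  s <- preset$sites
  C <- preset$calibration_concentration
  if (any(s$E_bound < 0 | s$E_bound > 1)) {
    stop("E_bound outside [0, 1] in preset ", preset$substrate)
  }
  if (preset$k_diff < 0) stop("negative k_diff in ", preset$substrate)
  tau_u <- 1 / (s$k_on * C)
  tau_b <- 1 / s$k_off
  kd_implied <- tau_u / (tau_b * C)
  rel <- abs(kd_implied - s$kd_target) / s$kd_target
  if (any(rel > tol)) {
    stop("calibration closure violated for ", preset$substrate, " (",
         paste(s$site[rel > tol], collapse = ", "), ")")
  }
  invisible(preset)
}

#' Serialize substrate specs or a whole library back to YAML
#'
#' Writing the bundled library and re-reading it reproduces the same specs,
#' which is the config round-trip guarantee used by the tests.
#'
#' @param config A config list as returned by [read_substrate_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_substrate_config <- function(config, path) {
  subs <- lapply(unname(config$substrates), function(s) {
    list(name = s$name,
         description = s$description,
         segments = lapply(seq_len(nrow(s$segments)), function(i) {
           list(kind = s$segments$kind[i], length = s$segments$length[i])
         }),
         junctions = lapply(seq_len(nrow(s$junctions)), function(i) {
           list(type = s$junctions$type[i], position = s$junctions$position[i])
         }),
         labels = s$labels,
         preset = s$preset_config)
  })
  out <- list(config_version = config$config_version,
              defaults = config$defaults,
              substrates = subs)
  writeLines(yaml::as.yaml(out, precision = 15), path)
  invisible(path)
}

#' @export
print.substrate_spec <- function(x, ...) {
  cat("<substrate_spec> ", x$name, "\n", sep = "")
  cat("  segments:  ",
      paste(sprintf("%s:%g", x$segments$kind, x$segments$length),
            collapse = " | "), "\n", sep = "")
  cat("  junctions: ",
      paste(sprintf("%s@%g", x$junctions$type, x$junctions$position),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.kinetic_preset <- function(x, ...) {
  cat("<kinetic_preset> ", x$substrate,
      "  (C_cal = ", x$calibration_concentration, " nM, ",
      x$cleavage$mode, " cleavage)\n", sep = "")
  print(x$sites, row.names = FALSE)
  if (x$k_diff > 0) cat("  k_diff = ", signif(x$k_diff, 4), " /s\n", sep = "")
  invisible(x)
}
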