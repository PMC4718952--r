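#' Two-chamber dialysis cassette geometry
#'
#' A dialysis insert holds a small sample chamber (antibody + tracer) and a
#' larger buffer chamber (competitive inhibitor), separated by a membrane that
#' passes small molecules but retains IgG. The defaults are the standard
#' single-use 48-insert plate format: 100 uL sample + 300 uL buffer.
#'
#' @param v_sample Sample-chamber volume in uL. Must be > 0.
#' @param v_buffer Buffer-chamber volume in uL. Must be > 0.
#'
#' @return An object of class `dialysis_geometry`: a list with elements
#'   `v_sample`, `v_buffer` and `v_total` (all uL).
#' @examples
#' dialysis_geometry()          # 100 + 300 = 400 uL insert
#' dialysis_geometry(150, 150)  # symmetric cassette
#' @export
dialysis_geometry <- function(v_sample = 100, v_buffer = 300) {
  stopifnot(is.numeric(v_sample), length(v_sample) == 1, is.finite(v_sample),
            is.numeric(v_buffer), length(v_buffer) == 1, is.finite(v_buffer))
  if (v_sample <= 0 || v_buffer <= 0) {
    rlang::abort("chamber volumes must be positive", class = "dialyzr_invalid")
  }
  structure(
    list(v_sample = v_sample, v_buffer = v_buffer,
         v_total = v_sample + v_buffer),
    class = "dialysis_geometry"
  )
}

#' @export
print.dialysis_geometry <- function(x, ...) {
  cat(sprintf("<dialysis_geometry> sample %g uL + buffer %g uL = %g uL\n",
              x$v_sample, x$v_buffer, x$v_total))
  invisible(x)
}

#' A membrane-permeant ligand (tracer or competitive inhibitor)
#'
#' Describes one small-molecule species in the cassette: its single-site
#' dissociation constant against the antibody (the *generative* affinity when
#' used to simulate assays), the substance amount loaded, and the chamber it
#' was loaded into. `kd_site = Inf` denotes a species the antibody does not
#' bind.
#'
#' @param name Identifier, e.g. `"d3-morphine"` or `"morphine"`. Deuterated
#'   tracers are conventionally named with a `"d3-"` prefix; degradation
#'   lookups strip the prefix, so a tracer decays like its parent drug.
#' @param kd_site Site dissociation constant in nM (> 0, or `Inf` for a
#'   non-binder).
#' @param amount Substance amount loaded, in nM*uL (concentration x volume).
#' @param chamber `"sample"` or `"buffer"`; where the ligand starts. At
#'   equilibrium only the amount matters, but time-course simulation needs it.
#'
#' @return An object of class `dialyzr_ligand`.
#' @examples
#' # 5 nM tracer in the 100 uL sample chamber:
#' ligand("d3-morphine", kd_site = 2, amount = 5 * 100)
#' @export
ligand <- function(name, kd_site = Inf, amount = 0,
                   chamber = c("sample", "buffer")) {
  chamber <- match.arg(chamber)
  stopifnot(is.character(name), length(name) == 1, nzchar(name),
            is.numeric(kd_site), length(kd_site) == 1,
            is.numeric(amount), length(amount) == 1, is.finite(amount))
  if (!(kd_site > 0)) {
    rlang::abort("kd_site must be > 0 (Inf for a non-binder)",
                 class = "dialyzr_invalid")
  }
  if (amount < 0) {
    rlang::abort("ligand amount must be >= 0", class = "dialyzr_invalid")
  }
  structure(list(name = name, kd_site = kd_site, amount = amount,
                 chamber = chamber),
            class = "dialyzr_ligand")
}

#' Convenience tracer constructor
#'
#' Builds the standard tracer loading: `conc_nM` of labeled drug in the sample
#' chamber. The default 5 nM in 100 uL is the assay's standard tracer dose.
#'
#' @param name Tracer identifier.
#' @param kd_site Site dissociation constant in nM.
#' @param conc_nM Loading concentration in the sample chamber (nM).
#' @param geometry A [dialysis_geometry()].
#' @return A `dialyzr_ligand` loaded in the sample chamber.
#' @examples
#' tracer_ligand("d3-morphine", kd_site = 2)
#' @export
tracer_ligand <- function(name = "d3-morphine", kd_site = Inf, conc_nM = 5,
                          geometry = dialysis_geometry()) {
  ligand(name, kd_site = kd_site, amount = conc_nM * geometry$v_sample,
         chamber = "sample")
}

#' Full physical description of one dialysis cassette
#'
#' Combines geometry, impermeant single-site antibody binding sites (confined
#' to the sample chamber) and up to two permeant ligands: a tracer and an
#' optional competitive inhibitor. Binding-site concentration is taken as the
#' nominal antibody concentration times `valence` (default 1, i.e. one
#' effective site per IgG, matching how affinity tables are computed from the
#' nominal antibody concentration).
#'
#' @param site_conc Antibody binding-site concentration in the sample chamber
#'   (nM, >= 0). Zero describes a negative-control cassette.
#' @param tracer A `dialyzr_ligand` for the tracer.
#' @param inhibitor Optional `dialyzr_ligand` for the competitive inhibitor.
#' @param geometry A [dialysis_geometry()].
#' @param valence Effective sites per antibody molecule (config multiplier,
#'   default 1).
#'
#' @return An object of class `binding_system`.
#' @examples
#' geo <- dialysis_geometry()
#' sys <- binding_system(
#'   site_conc = 2.4,
#'   tracer    = tracer_ligand("d3-morphine", kd_site = 2, conc_nM = 5),
#'   inhibitor = ligand("morphine", kd_site = 2, amount = 1333.3 * 300,
#'                      chamber = "buffer"),
#'   geometry  = geo
#' )
#' sys
#' @export
binding_system <- function(site_conc, tracer, inhibitor = NULL,
                           geometry = dialysis_geometry(), valence = 1) {
  stopifnot(inherits(geometry, "dialysis_geometry"),
            inherits(tracer, "dialyzr_ligand"),
            is.numeric(site_conc), length(site_conc) == 1,
            is.finite(site_conc),
            is.numeric(valence), length(valence) == 1, valence > 0)
  if (site_conc < 0) {
    rlang::abort("site_conc must be >= 0", class = "dialyzr_invalid")
  }
  if (!is.null(inhibitor)) stopifnot(inherits(inhibitor, "dialyzr_ligand"))
  structure(
    list(geometry = geometry,
         site_conc = site_conc * valence,
         tracer = tracer,
         inhibitor = inhibitor),
    class = "binding_system"
  )
}

#' @export
print.binding_system <- function(x, ...) {
  cat("<binding_system>\n")
  cat(sprintf("  geometry : %g + %g uL\n",
              x$geometry$v_sample, x$geometry$v_buffer))
  cat(sprintf("  sites    : %g nM (sample chamber, impermeant)\n",
              x$site_conc))
  cat(sprintf("  tracer   : %s, Kd %g nM, %g nM*uL in %s chamber\n",
              x$tracer$name, x$tracer$kd_site, x$tracer$amount,
              x$tracer$chamber))
  if (is.null(x$inhibitor)) {
    cat("  inhibitor: none\n")
  } else {
    cat(sprintf("  inhibitor: %s, Kd %g nM, %g nM*uL in %s chamber\n",
                x$inhibitor$name, x$inhibitor$kd_site, x$inhibitor$amount,
                x$inhibitor$chamber))
  }
  invisible(x)
}
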