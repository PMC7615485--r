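# ABA triblock copolymer and blend bookkeeping.
#
# Copolymers are PMOXA-b-PDMS-b-PMOXA triblocks named "A-B-A" where the
# integers are the degrees of polymerization (DP) of the hydrophilic PMOXA
# arms and the hydrophobic PDMS mid-block, e.g. "6-65-6". Only symmetric
# architectures are supported.

# repeat-unit molar masses, g/mol
.MOXA_UNIT_MASS <- 85.10
.DMS_UNIT_MASS <- 74.15

#' Construct an ABA triblock copolymer
#'
#' @param name text label, conventionally `"A-B-A"` (DPs of the blocks).
#' @param dp_hydrophilic_per_arm integer DP of each hydrophilic (MOXA) arm.
#' @param dp_hydrophobic integer DP of the hydrophobic (DMS) mid-block.
#' @param mass_hydrophilic_unit repeat-unit molar mass of the hydrophilic
#'   block, g/mol (default 85.10 for 2-methyl-2-oxazoline).
#' @param mass_hydrophobic_unit repeat-unit molar mass of the hydrophobic
#'   block, g/mol (default 74.15 for dimethylsiloxane).
#' @param end_group_mass_hydrophilic molar mass attributed to hydrophilic
#'   end groups, g/mol; counted with the hydrophilic portion. Default 0.
#' @return an object of class `copolymer`.
#' @seealso [parse_copolymer_name()], [hydrophilic_fraction()]
#' @export
copolymer <- function(name, dp_hydrophilic_per_arm, dp_hydrophobic,
                      mass_hydrophilic_unit = .MOXA_UNIT_MASS,
                      mass_hydrophobic_unit = .DMS_UNIT_MASS,
                      end_group_mass_hydrophilic = 0) {
  dp_a <- as.integer(dp_hydrophilic_per_arm)
  dp_b <- as.integer(dp_hydrophobic)
  if (is.na(dp_a) || is.na(dp_b) || dp_a < 1L || dp_b < 1L)
    stop("degrees of polymerization must be integers >= 1")
  if (!is.numeric(mass_hydrophilic_unit) || mass_hydrophilic_unit <= 0 ||
      !is.numeric(mass_hydrophobic_unit) || mass_hydrophobic_unit <= 0)
    stop("repeat-unit masses must be > 0")
  if (end_group_mass_hydrophilic < 0)
    stop("end-group mass must be >= 0")
  structure(list(
    name = as.character(name),
    dp_hydrophilic_per_arm = dp_a,
    dp_hydrophobic = dp_b,
    mass_hydrophilic_unit = mass_hydrophilic_unit,
    mass_hydrophobic_unit = mass_hydrophobic_unit,
    end_group_mass_hydrophilic = end_group_mass_hydrophilic
  ), class = "copolymer")
}

#' Parse an "A-B-A" copolymer name
#'
#' Parses names such as `"6-65-6"` (PMOXA_6-b-PDMS_65-b-PMOXA_6). The first
#' and last integers must match: asymmetric triblocks are rejected.
#'
#' @param name the `"A-B-A"` name.
#' @param unit_masses length-2 numeric, repeat-unit masses g/mol in the order
#'   (hydrophilic, hydrophobic).
#' @param end_group_mass_hydrophilic optional end-group mass, g/mol.
#' @return a [copolymer()].
#' @export
parse_copolymer_name <- function(name,
                                 unit_masses = c(.MOXA_UNIT_MASS, .DMS_UNIT_MASS),
                                 end_group_mass_hydrophilic = 0) {
  if (!is.character(name) || length(name) != 1L)
    stop("'name' must be a single character string")
  if (!grepl("^[0-9]+-[0-9]+-[0-9]+$", name))
    stop(sprintf("malformed copolymer name '%s': expected 'A-B-A' integers", name))
  dps <- as.integer(strsplit(name, "-", fixed = TRUE)[[1L]])
  if (dps[1L] != dps[3L])
    stop(sprintf("unsupported architecture '%s': A blocks differ (%d vs %d); only symmetric ABA is supported",
                 name, dps[1L], dps[3L]))
  copolymer(name, dps[1L], dps[2L],
            mass_hydrophilic_unit = unit_masses[[1L]],
            mass_hydrophobic_unit = unit_masses[[2L]],
            end_group_mass_hydrophilic = end_group_mass_hydrophilic)
}

#' Total molar mass of a copolymer chain
#'
#' @param x a [copolymer()].
#' @return molar mass, g/mol: `2*dp_A*m_A + dp_B*m_B + end groups`.
#' @export
molar_mass <- function(x) {
  stopifnot(inherits(x, "copolymer"))
  2 * x$dp_hydrophilic_per_arm * x$mass_hydrophilic_unit +
    x$dp_hydrophobic * x$mass_hydrophobic_unit +
    x$end_group_mass_hydrophilic
}

#' Hydrophilic weight fraction of an ABA copolymer
#'
#' Weight percentage of the hydrophilic blocks (both arms plus any
#' hydrophilic end-group mass) relative to the whole chain. Triblocks with
#' f_hydrophilic around 35 +/- 10 % tend to self-assemble into vesicles
#' rather than micelles; this function only reports the number, it does not
#' enforce that window.
#'
#' @param x a [copolymer()].
#' @return percent in (0, 100).
#' @export
hydrophilic_fraction <- function(x) {
  stopifnot(inherits(x, "copolymer"))
  m_phil <- 2 * x$dp_hydrophilic_per_arm * x$mass_hydrophilic_unit +
    x$end_group_mass_hydrophilic
  100 * m_phil / molar_mass(x)
}

#' Construct a copolymer blend
#'
#' @param components list of [copolymer()] objects.
#' @param mole_fractions numeric, same length, each >= 0, summing to 1
#'   (within 1e-9).
#' @param description optional text.
#' @return an object of class `blend`.
#' @export
blend <- function(components, mole_fractions, description = "") {
  if (length(components) == 0L) stop("empty blend")
  if (!all(vapply(components, inherits, logical(1), "copolymer")))
    stop("all blend components must be copolymer objects")
  x <- as.numeric(mole_fractions)
  if (length(x) != length(components)) stop("one mole fraction per component required")
  if (any(x < 0)) stop("mole fractions must be >= 0")
  if (abs(sum(x) - 1) > 1e-9) stop("mole fractions must sum to 1")
  structure(list(components = components, mole_fractions = x,
                 description = as.character(description)), class = "blend")
}

#' Summarise a copolymer blend
#'
#' Per-component mole and mass fractions plus the mole-weighted mean
#' hydrophilic DP. Mass fractions are computed from chain molar masses:
#' `w_i = x_i M_i / sum(x_j M_j)`.
#'
#' @param b a [blend()].
#' @return a `data.frame` with columns `name`, `mole_fraction`,
#'   `mass_fraction`, `molar_mass`, `dp_hydrophilic_per_arm`,
#'   `hydrophilic_fraction`, and attributes `mean_dp_hydrophilic_per_arm`
#'   (mole-weighted mean PMOXA DP per arm) and `mean_dp_hydrophilic_per_chain`
#'   (twice that, both arms).
#' @export
blend_summary <- function(b) {
  stopifnot(inherits(b, "blend"))
  mm <- vapply(b$components, molar_mass, numeric(1))
  x <- b$mole_fractions
  w <- x * mm / sum(x * mm)
  dpa <- vapply(b$components, function(cp) as.numeric(cp$dp_hydrophilic_per_arm), numeric(1))
  out <- data.frame(
    name = vapply(b$components, function(cp) cp$name, character(1)),
    mole_fraction = x,
    mass_fraction = w,
    molar_mass = mm,
    dp_hydrophilic_per_arm = dpa,
    hydrophilic_fraction = vapply(b$components, hydrophilic_fraction, numeric(1)),
    stringsAsFactors = FALSE
  )
  attr(out, "mean_dp_hydrophilic_per_arm") <- sum(x * dpa)
  attr(out, "mean_dp_hydrophilic_per_chain") <- 2 * sum(x * dpa)
  out
}

#' @export
print.copolymer <- function(x, ...) {
  cat(sprintf("ABA copolymer %s: %d-%d-%d, f_hydrophilic = %.1f%% (M = %.0f g/mol)\n",
              x$name, x$dp_hydrophilic_per_arm, x$dp_hydrophobic,
              x$dp_hydrophilic_per_arm, hydrophilic_fraction(x), molar_mass(x)))
  invisible(x)
}

#' @export
print.blend <- function(x, ...) {
  s <- blend_summary(x)
  cat(sprintf("Copolymer blend (%s): %s\n",
              if (nzchar(x$description)) x$description else "unnamed",
              paste(sprintf("%s %.0f mol%%", s$name, 100 * s$mole_fraction),
                    collapse = " : ")))
  cat(sprintf("  mean hydrophilic DP per arm: %.2f\n",
              attr(s, "mean_dp_hydrophilic_per_arm")))
  invisible(x)
}
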