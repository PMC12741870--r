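# Ethos plan naming grammar.
#
# Daily adaptive sessions are named "[Reference Plan ID]/[SCH|ADP][2-digit
# fraction][2-digit suffix]". The two-digit suffix advances by two with every
# structure-set revision, so a revision holds a consecutive suffix pair: the
# default session pair for reference plan IM103 on fraction 14 is
# IM103/SCH1401 + IM103/ADP1402, and a contour re-edit spawns IM103/SCH1403 +
# IM103/ADP1404. Within a pair SCH/ADP may hold either suffix. A name with no
# /SCH or /ADP token is the reference plan itself.

#' Parse an Ethos plan name
#'
#' Splits a plan name into its components: reference plan ID, plan type
#' (reference, scheduled or adaptive), fraction number, printed suffix and the
#' structure-set revision implied by the suffix (`revision = ceiling(suffix/2)`,
#' because each revision spawns a consecutive suffix pair).
#'
#' Names without a `/SCH` or `/ADP` segment are classified as the reference
#' plan with `fraction`, `suffix` and `revision` set to `NA`. Fraction numbers
#' wider than two digits are accepted on parse (the last two trailing digits
#' are always the suffix); [format_plan_name()] refuses them.
#'
#' @param name Plan name string (the source document's `planName_str` field).
#' @return An object of class `plan_identity`: a list with fields
#'   `reference_id`, `plan_type` (`"reference"`, `"scheduled"` or
#'   `"adaptive"`), `fraction`, `suffix`, `revision` and `site` (optional,
#'   `NA` unless supplied downstream).
#' @examples
#' parse_plan_name("IM103/SCH1401")  # fraction 14, revision 1
#' parse_plan_name("IM103/ADP1403")  # revision 2
#' parse_plan_name("IM103")          # reference plan
#' @seealso [format_plan_name()], [build_course()]
#' @export
parse_plan_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name)) {
    oartex_error("plan name must be a non-empty string", "oartex_malformed_name")
  }
  m <- regexec("^(.*)/(SCH|ADP)([0-9]*)$", name)[[1]]
  if (m[1] == -1L) {
    # No session token: the reference plan.
    return(new_plan_identity(reference_id = name, plan_type = "reference",
                             fraction = NA_integer_, suffix = NA_integer_))
  }
  parts <- regmatches(name, list(regexec("^(.*)/(SCH|ADP)([0-9]*)$", name)[[1]]))[[1]]
  ref_id <- parts[2]
  token <- parts[3]
  digits <- parts[4]
  if (nchar(digits) < 4L) {
    oartex_error(sprintf("malformed plan name '%s': %s token needs >= 4 trailing digits",
                         name, token),
                 "oartex_malformed_name", name = name)
  }
  suffix <- as.integer(substr(digits, nchar(digits) - 1L, nchar(digits)))
  fraction <- as.integer(substr(digits, 1L, nchar(digits) - 2L))
  if (suffix < 1L || fraction < 1L) {
    oartex_error(sprintf("malformed plan name '%s': fraction and suffix must be >= 1", name),
                 "oartex_malformed_name", name = name)
  }
  new_plan_identity(
    reference_id = ref_id,
    plan_type = if (token == "SCH") "scheduled" else "adaptive",
    fraction = fraction, suffix = suffix
  )
}

new_plan_identity <- function(reference_id, plan_type, fraction, suffix,
                              site = NA_character_) {
  revision <- if (is.na(suffix)) NA_integer_ else as.integer(ceiling(suffix / 2))
  structure(list(reference_id = reference_id, plan_type = plan_type,
                 fraction = fraction, suffix = suffix, revision = revision,
                 site = site),
            class = "plan_identity")
}

#' @export
print.plan_identity <- function(x, ...) {
  if (x$plan_type == "reference") {
    cat(sprintf("<plan_identity> %s (reference plan)\n", x$reference_id))
  } else {
    cat(sprintf("<plan_identity> %s  %s plan, fraction %d, structure-set revision %d (suffix %02d)\n",
                x$reference_id, x$plan_type, x$fraction, x$revision, x$suffix))
  }
  invisible(x)
}

#' Format a plan identity back into its Ethos name
#'
#' Inverse of [parse_plan_name()] on grammar-conformant names: fraction and
#' suffix are zero-padded to two digits. Reference identities format to the
#' bare reference plan ID.
#'
#' @param identity A `plan_identity` object.
#' @return The plan name string.
#' @export
format_plan_name <- function(identity) {
  stopifnot(inherits(identity, "plan_identity"))
  if (identity$plan_type == "reference") return(identity$reference_id)
  if (is.na(identity$fraction) || is.na(identity$suffix)) {
    oartex_error("scheduled/adaptive identity needs fraction and suffix",
                 "oartex_format_error")
  }
  if (identity$fraction > 99L || identity$suffix > 99L) {
    # The grammar fixes two digits for each field; wider values have no
    # printable form even though parse accepts them.
    oartex_error(sprintf("fraction/suffix above 99 cannot be formatted (fraction=%d, suffix=%d)",
                         identity$fraction, identity$suffix),
                 "oartex_format_error")
  }
  token <- if (identity$plan_type == "scheduled") "SCH" else "ADP"
  sprintf("%s/%s%02d%02d", identity$reference_id, token,
          identity$fraction, identity$suffix)
}

#' Plan complexity summary
#'
#' Aggregates per-beam monitor units and control points into simple plan
#' complexity measures. Detailed aperture metrics are out of reach for this
#' data source (MLC positions per control point are not exposed), so the
#' modulation factor used here is total MU normalised by the fraction
#' prescription dose in cGy — a dimensionless surrogate for how heavily
#' modulated the delivery is relative to an open field.
#'
#' @param beams List of beam entries, each a list with at least `mu` and
#'   `n_control_points` fields (as produced by [fetch_check()]).
#' @param prescription_cgy Fraction prescription dose in cGy; must be > 0.
#' @return A list of class `complexity_summary` with `total_mu`,
#'   `modulation_factor`, `n_control_points` and `n_beams`.
#' @examples
#' b <- list(list(mu = 400, n_control_points = 100),
#'           list(mu = 350, n_control_points = 120))
#' plan_complexity(b, prescription_cgy = 250)$modulation_factor  # 3
#' @export
plan_complexity <- function(beams, prescription_cgy) {
  assert_scalar_number(prescription_cgy, "prescription_cgy", min = 0, strict_min = TRUE)
  mu <- vapply(beams, function(b) as.numeric(b$mu %||% 0), numeric(1))
  if (any(mu < 0)) oartex_error("beam MU must be >= 0", "oartex_domain_error")
  ncp <- vapply(beams, function(b) as.integer(b$n_control_points %||% 0L), integer(1))
  structure(list(
    total_mu = sum(mu),
    modulation_factor = sum(mu) / prescription_cgy,
    n_control_points = sum(ncp),
    n_beams = length(beams)
  ), class = "complexity_summary")
}
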