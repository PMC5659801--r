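# Model variants: the basic trafficking network extended by optional parts
# A (direct recycling EpoR*_RE -> EpoR_m), B (recycling to the intracellular
# pool with intracellular accumulation of degraded Epo), C (degradation with
# export of degraded Epo) and D (degradation with intracellular accumulation).

.PARAM_NAMES <- c(
  "k_on_Epo", "k_off_Epo", "k_EpoR_syn", "k_EpoR_deg",
  "k_EpoR_ItoM", "k_EpoR_MtoI", "k_EpoRstar_MtoRE",
  "k_EpoRstar_REtoM", "k_EpoRstar_REtoI",
  "k_EpoRstar_deg_REtoEx", "k_EpoRstar_deg_REtoI", "k_bleach"
)

.PART_PARAMS <- c(A = "k_EpoRstar_REtoM", B = "k_EpoRstar_REtoI",
                  C = "k_EpoRstar_deg_REtoEx", D = "k_EpoRstar_deg_REtoI")

.STATE_NAMES <- c("EpoR_i", "EpoR_m", "EpoRstar_m", "EpoRstar_RE",
                  "Epo_deg_i", "Epo_deg_ext")

#' Construct a trafficking model variant
#'
#' A variant is identified by which of the optional parts A--D extend the
#' basic membrane/intracellular receptor turnover network. The canonical name
#' is the sorted string of present letters (`""` for the basic model).
#'
#' @param name Character such as `""`, `"A"`, `"ACD"`, `"ABCD"`; letters may
#'   be given in any order.
#' @return An object of class `epor_variant` with logical fields `has_A` ..
#'   `has_D` and the canonical `name`.
#' @examples
#' epor_variant("ACD")
#' @export
epor_variant <- function(name = "") {
  if (inherits(name, "epor_variant")) return(name)
  stopifnot(is.character(name), length(name) == 1L)
  letters_in <- if (nzchar(name)) strsplit(toupper(name), "")[[1]] else character()
  bad <- setdiff(letters_in, c("A", "B", "C", "D"))
  if (length(bad) > 0)
    stop("unknown model part(s): ", paste(bad, collapse = ", "))
  letters_in <- sort(unique(letters_in))
  structure(
    list(name = paste(letters_in, collapse = ""),
         has_A = "A" %in% letters_in, has_B = "B" %in% letters_in,
         has_C = "C" %in% letters_in, has_D = "D" %in% letters_in),
    class = "epor_variant")
}

#' Enumerate all 16 model variants
#'
#' Returns every subset of the optional parts \{A, B, C, D\} as a variant,
#' deterministically ordered by canonical name (basic model first).
#'
#' @return A list of 16 `epor_variant` objects.
#' @export
epor_variants <- function() {
  grid <- expand.grid(A = c(FALSE, TRUE), B = c(FALSE, TRUE),
                      C = c(FALSE, TRUE), D = c(FALSE, TRUE))
  names_all <- apply(grid, 1, function(row)
    paste(c("A", "B", "C", "D")[as.logical(row)], collapse = ""))
  lapply(names_all[order(names_all)], epor_variant)
}

#' @export
print.epor_variant <- function(x, ...) {
  nm <- if (nzchar(x$name)) x$name else "basic"
  cat("EpoR trafficking model variant:", nm, "\n")
  cat("  parts: A(recycle RE->membrane)=", x$has_A,
      " B(recycle RE->pool)=", x$has_B,
      " C(degrade, Epo exported)=", x$has_C,
      " D(degrade, Epo accumulates)=", x$has_D, "\n", sep = "")
  cat("  kinetic parameters (Epo condition):",
      n_kinetic_params(x, "epo"), "\n")
  invisible(x)
}

#' Kinetic parameter names of a model
#'
#' @param variant An `epor_variant` or variant name (ignored for the reduced
#'   bleach/CHX models).
#' @param condition `"epo"`, `"bleach"` or `"chx"`.
#' @return Character vector of kinetic parameter names for that condition's
#'   model, globals (`k_on_Epo`, `k_off_Epo`) included for `"epo"`.
#' @export
kinetic_param_names <- function(variant = "", condition = "epo") {
  condition <- match.arg(condition, c("epo", "bleach", "chx"))
  if (condition == "bleach")
    return(c("k_EpoR_syn", "k_EpoR_deg", "k_EpoR_ItoM", "k_EpoR_MtoI",
             "k_bleach"))
  if (condition == "chx")
    return(c("k_EpoR_deg", "k_EpoR_ItoM", "k_EpoR_MtoI"))
  v <- epor_variant(variant)
  base <- c("k_on_Epo", "k_off_Epo", "k_EpoR_syn", "k_EpoR_deg",
            "k_EpoR_ItoM", "k_EpoR_MtoI", "k_EpoRstar_MtoRE")
  extra <- .PART_PARAMS[c(v$has_A, v$has_B, v$has_C, v$has_D)]
  c(base, unname(extra))
}

#' @rdname kinetic_param_names
#' @export
n_kinetic_params <- function(variant = "", condition = "epo")
  length(kinetic_param_names(variant, condition))

# Validate a named kinetic parameter vector against a variant/condition model
# and expand it to the fixed 12-slot layout used by the solver. Parameters
# the model excludes are a structural error, not silently zeroed.
as_param_vector <- function(params, variant = "", condition = "epo") {
  allowed <- kinetic_param_names(variant, condition)
  nm <- names(params)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("kinetic parameters must be a fully named vector")
  extra <- setdiff(nm, allowed)
  if (length(extra) > 0)
    stop("parameter(s) not part of this model: ", paste(extra, collapse = ", "))
  missing <- setdiff(allowed, nm)
  if (length(missing) > 0)
    stop("missing kinetic parameter(s): ", paste(missing, collapse = ", "))
  if (any(!is.finite(params)) || any(params < 0))
    stop("kinetic parameters must be finite and >= 0")
  full <- setNames(numeric(length(.PARAM_NAMES)), .PARAM_NAMES)
  full[nm] <- params
  full
}
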