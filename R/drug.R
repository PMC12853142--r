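# Drug-specific ADME parameters and the pathway partition.
#
# The bundled configs give the adult fraction metabolised per pathway (fm)
# rather than intrinsic clearances; the loader back-calculates whole-liver
# and per-mg-microsomal-protein unbound intrinsic clearances from the adult
# fm targets, the total adult clearance and the packaged adult physiology,
# so that the well-stirred model reproduces the configured partition in a
# typical adult exactly.

# µL/min (whole liver) -> L/h
UL_MIN_TO_L_H <- 60 / 1e6

#' Load a drug parameter configuration
#'
#' Reads a structured YAML drug block (or an equivalent list): absorption
#' (`FaFg`, `ka`), distribution (`V_ref`, allometric exponent), binding
#' (`fu`, `BP`), the adult clearance and its pathway partition, and the
#' ontogeny binding of every pathway (a fixed profile name or an inline
#' `family`/`parameters` block). Adult per-pathway unbound intrinsic
#' clearances are back-calculated from the partition via the well-stirred
#' liver model and stored both as whole-liver L/h and as
#' µL/min/mg microsomal protein.
#'
#' @param config Path to a YAML file, or a list with the same fields.
#' @return An object of class `drug_parameters`.
#' @export
#' @examples
#' drug <- load_drug_config(example_drug_path())
#' drug$fm_adult_target
load_drug_config <- function(config = example_drug_path()) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (req in c("FaFg", "ka", "V_ref", "fu", "BP", "adult_CL_total",
                "fe_renal", "pathways")) {
    if (is.null(cfg[[req]])) stopf("drug config lacks field '%s'", req)
  }
  assert_number(cfg$FaFg, "FaFg", lower = 0, upper = 1, strict_lower = TRUE)
  assert_number(cfg$ka, "ka", lower = 0, strict_lower = TRUE)
  assert_number(cfg$V_ref, "V_ref", lower = 0, strict_lower = TRUE)
  assert_number(cfg$fu, "fu", lower = 0, upper = 1, strict_lower = TRUE)
  assert_number(cfg$BP, "BP", lower = 0, strict_lower = TRUE)
  assert_number(cfg$fe_renal, "fe_renal", lower = 0, upper = 1)
  fm <- vapply(cfg$pathways, function(p) as.numeric(p$fm_adult), 0)
  if (any(fm < 0) || length(fm) < 1L) {
    stopf("each pathway needs fm_adult >= 0, and at least one pathway")
  }
  if (abs(sum(fm) + cfg$fe_renal - 1) > 1e-9) {
    stopf("adult fm values plus fe_renal must sum to 1 (got %.6f)",
          sum(fm) + cfg$fe_renal)
  }
  fu_B <- cfg$fu / cfg$BP
  adult <- adult_reference_profile()

  cl_total <- cfg$adult_CL_total
  cl_r <- cfg$fe_renal * cl_total
  cl_h <- cl_total - cl_r
  if (cl_h >= adult$Q_H) stopf("adult hepatic clearance exceeds liver flow")
  # invert the well-stirred model for the whole-liver unbound CL_int
  clint_total <- adult$Q_H * cl_h / (fu_B * (adult$Q_H - cl_h))
  shares <- fm / sum(fm)
  clint_pathway <- clint_total * shares
  scaling_mg <- adult$MPPGL * adult$liver_weight     # mg microsomal protein
  clint_per_mg <- clint_pathway / (scaling_mg * UL_MIN_TO_L_H)

  resolve_binding <- function(x) {
    if (is.character(x)) fixed_profile(x) else ontogeny_from_config(x)
  }
  bindings <- lapply(cfg$pathways, function(p) resolve_binding(p$ontogeny))
  renal <- if (!is.null(cfg$renal_ontogeny)) {
    resolve_binding(cfg$renal_ontogeny)
  } else flat_ontogeny()

  structure(list(
    name = cfg$name %||% "drug",
    FaFg = cfg$FaFg, ka = cfg$ka,
    V_ref = cfg$V_ref,
    vol_allometric_exponent = cfg$vol_allometric_exponent %||% 1.0,
    fu = cfg$fu, BP = cfg$BP, fu_B = fu_B,
    CLR_adult = cl_r,
    CLint_adult_total = clint_total,
    CLint_pathway = clint_pathway,
    CLint_per_mg = clint_per_mg,
    fm_adult_target = c(fm, renal = cfg$fe_renal),
    pathway_ontogeny = bindings,
    renal_ontogeny = renal,
    adult_profile = adult
  ), class = "drug_parameters")
}

#' Path to the bundled risdiplam-like example drug configuration
#' @return File path.
#' @export
example_drug_path <- function() onto_extdata("risdiplam_like.yaml")

#' @export
print.drug_parameters <- function(x, ...) {
  cat(sprintf("<drug_parameters '%s'>\n", x$name))
  cat(sprintf("  FaFg %.3g, ka %.3g /h, V_ref %.4g L, fu %.3g, B:P %.3g\n",
              x$FaFg, x$ka, x$V_ref, x$fu, x$BP))
  cat(sprintf("  adult whole-liver CL_int %.4g L/h (%s), CL_R %.3g L/h\n",
              x$CLint_adult_total,
              paste(sprintf("%s %.3g", names(x$CLint_pathway),
                            x$CLint_pathway), collapse = ", "),
              x$CLR_adult))
  invisible(x)
}

#' Rebind one pathway's ontogeny (e.g. with estimated parameters)
#'
#' @param drug A `drug_parameters` object.
#' @param pathway Pathway name present in the drug config.
#' @param model,params The replacement ontogeny model and parameters.
#' @return The modified `drug_parameters` object.
#' @export
set_pathway_ontogeny <- function(drug, pathway, model, params) {
  if (!pathway %in% names(drug$pathway_ontogeny)) {
    stopf("pathway '%s' not in drug config (%s)", pathway,
          paste(names(drug$pathway_ontogeny), collapse = ", "))
  }
  drug$pathway_ontogeny[[pathway]] <-
    list(model = model, params = as_ontogeny_parameters(params))
  drug
}
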