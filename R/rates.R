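#' Base constant rates (BCR) of the IIR network
#'
#' The reaction network is parameterized by a small table of base constant
#' rates: one rate per reaction *class* (translation, degradation, binding,
#' gene activation, ...). Every individual reaction refers to one BCR entry
#' and carries a dimensionless per-reaction coefficient, so that its rate
#' constant is \code{BCR * coefficient}. This factorization is what the
#' staged coefficient refinement in [refine_coefficients()] operates on.
#'
#' Units: first-order entries are 1/s, second-order entries are
#' 1/(molecule s); \code{siRNA_incr_degr_r}, \code{prot_avg} and
#' \code{cyto_to_nuc_ratio} are dimensionless/auxiliary.
#'
#' @param ... named overrides of individual entries, e.g.
#'   \code{bcr_table(mRNA_degr_r = 2e-4)}.
#' @return A named list of class \code{"bcr_table"} with the 21 entries.
#' @export
#' @examples
#' rates <- bcr_table()
#' rates$prot_transl_r
bcr_table <- function(...) {
  tab <- list(
    prot_transl_r        = 5e-2,  # protein translation, 1/s per mRNA
    prot_unreg_transl_r  = 5e-1,  # unregulated (constitutive) protein source
    prot_degr_r          = 1e-5,  # protein degradation
    prot_unreg_degr_r    = 1e-4,  # unregulated protein degradation
    prot_phosph_degr_r   = 3e-4,  # degradation of phosphorylated/active protein
    prot_bind_r          = 1e-7,  # protein-protein binding, 1/(#mol s)
    prot_activ_r         = 1e-8,  # phosphorylation/activation, 1/(#mol s)
    prot_transition_r    = 1e-4,  # conformational/maturation transition
    prot_diss_r          = 1e-6,  # complex dissociation
    prot_import_r        = 1e-3,  # nuclear import
    prot_export_r        = 1e-3,  # nuclear export
    dsRNA_recogn_r       = 1e-9,  # receptor binding to dsRNA, 1/(#mol s)
    dsRNA_degr_r         = 1e-9,  # dsRNA-induced protein degradation, 1/(#mol s)
    gene_act_r           = 1e-7,  # TF binding to gene copy, 1/(#mol s)
    gene_inact_r         = 1e-2,  # TF unbinding from gene copy
    mRNA_transc_r        = 5e-2,  # transcription from an activated gene copy
    mRNA_basal_transc_r  = 1e-3,  # basal transcription from a free gene copy
    mRNA_degr_r          = 1e-4,  # mRNA degradation
    siRNA_incr_degr_r    = 10,    # mRNA-degradation increment factor under siRNA
    prot_avg             = 1e5,   # average protein copy number (scaling constant)
    cyto_to_nuc_ratio    = 5      # cytoplasmic to nuclear volume ratio
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(tab))
    if (length(bad))
      stop("unknown BCR entrie(s): ", paste(bad, collapse = ", "))
    tab[names(ov)] <- ov
  }
  validate_bcr(tab)
  structure(tab, class = "bcr_table")
}

validate_bcr <- function(tab) {
  needed <- c("prot_transl_r", "prot_unreg_transl_r", "prot_degr_r",
              "prot_unreg_degr_r", "prot_phosph_degr_r", "prot_bind_r",
              "prot_activ_r", "prot_transition_r", "prot_diss_r",
              "prot_import_r", "prot_export_r", "dsRNA_recogn_r",
              "dsRNA_degr_r", "gene_act_r", "gene_inact_r", "mRNA_transc_r",
              "mRNA_basal_transc_r", "mRNA_degr_r", "siRNA_incr_degr_r",
              "prot_avg", "cyto_to_nuc_ratio")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("missing BCR entrie(s): ", paste(missing, collapse = ", "))
  vals <- unlist(tab[needed])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all BCR entries must be finite and > 0")
  invisible(tab)
}
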