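## Functional profiling: fraction of each KEGG module's KO terms found in
## each genome bin (the energy-metabolism heat-map statistic).

#' Per-bin KEGG-module KO ratios
#'
#' For every bin and module, the number of the module's KO terms present in
#' the bin divided by the module's total KO count.  KO multiplicity is
#' ignored (set semantics): a KO assigned to several genes of a bin counts
#' once.  Ratios are deliberately *not* normalized by genome size or
#' completeness, which would inflate the apparent importance of genes from
#' small genomes.
#'
#' @param bin_kos named list: bin_id -> character vector of KO identifiers
#' @param modules named list of module definitions (see
#'   [read_module_definitions()]), each with `module_id` and non-empty
#'   `ko_terms`
#' @return numeric matrix of fractions in `[0, 1]`, bins in rows, modules in
#'   columns
#' @export
compute_module_ratios <- function(bin_kos, modules) {
  if (length(modules) == 0) stop("no module definitions")
  for (m in modules)
    if (length(m$ko_terms) == 0) stop("module ", m$module_id, " has no KO terms")
  out <- matrix(0, length(bin_kos), length(modules),
                dimnames = list(names(bin_kos),
                                vapply(modules, `[[`, "", "module_id")))
  for (b in seq_along(bin_kos)) {
    kos <- unique(bin_kos[[b]])
    out[b, ] <- vapply(modules, function(m)
      length(intersect(kos, m$ko_terms)) / length(unique(m$ko_terms)), 1)
  }
  out
}
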