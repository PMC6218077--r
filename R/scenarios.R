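#' Gene lineage tags used in the duplication/loss hypotheses
#'
#' The seven observed intron-less rh1 gene lineages of teleosts: the
#' elopomorph "deep-sea" and "freshwater" paralogs, the two Hiodon copies,
#' the remaining osteoglossomorph copy, and the two clupeocephalan copies.
#'
#' @return Character vector of the seven lineage tags.
#' @export
lineage_tags <- function() {
  c("Elops_dso", "Elops_fwo", "Hiodon_rh1_1", "Hiodon_rh1_2",
    "Osteo_rh1", "Clupeo_rh1_A", "Clupeo_rh1_B")
}

#' Duplication/loss scenario identifiers
#'
#' Scenario family A places three duplications, B two, C one (the single
#' C-family duplication coincides with the fish-specific genome duplication
#' on the teleost stem).
#'
#' @return Character vector `A1, A2, B1..B6, C1..C4`.
#' @export
scenario_ids <- function() {
  c("A1", "A2", paste0("B", 1:6), paste0("C", 1:4))
}

#' @rdname scenario_ids
#' @param scenario_id One of [scenario_ids()].
#' @export
scenario_dup_count <- function(scenario_id) {
  fam <- substr(scenario_id, 1, 1)
  counts <- c(A = 3L, B = 2L, C = 1L)
  if (!fam %in% names(counts) || !scenario_id %in% scenario_ids()) {
    stop("unknown scenario id: ", scenario_id)
  }
  counts[[fam]]
}

# Rooted lineage-level gene-family topology for each scenario. Within each
# family the variants differ in which paralog lineage tracks which duplicate
# copy; B6 follows the observed gene tree (Elops_dso groups with
# Hiodon_rh1_2).
.scenario_newick <- c(
  A1 = "((Elops_dso,Elops_fwo),(((Hiodon_rh1_1,Osteo_rh1),Hiodon_rh1_2),(Clupeo_rh1_A,Clupeo_rh1_B)));",
  A2 = "(Elops_dso,(Elops_fwo,(((Hiodon_rh1_1,Osteo_rh1),Hiodon_rh1_2),(Clupeo_rh1_A,Clupeo_rh1_B))));",
  B1 = "((Elops_dso,Elops_fwo),(((Hiodon_rh1_1,Osteo_rh1),Clupeo_rh1_A),(Hiodon_rh1_2,Clupeo_rh1_B)));",
  B2 = "((Elops_dso,Elops_fwo),(((Hiodon_rh1_1,Osteo_rh1),Clupeo_rh1_B),(Hiodon_rh1_2,Clupeo_rh1_A)));",
  B3 = "(Elops_dso,(Elops_fwo,(((Hiodon_rh1_1,Osteo_rh1),Clupeo_rh1_A),(Hiodon_rh1_2,Clupeo_rh1_B))));",
  B4 = "(Elops_dso,(Elops_fwo,(((Hiodon_rh1_1,Osteo_rh1),Clupeo_rh1_B),(Hiodon_rh1_2,Clupeo_rh1_A))));",
  B5 = "((Elops_fwo,Hiodon_rh1_2),(Elops_dso,((Hiodon_rh1_1,Osteo_rh1),(Clupeo_rh1_A,Clupeo_rh1_B))));",
  B6 = "((Elops_dso,Hiodon_rh1_2),(Elops_fwo,((Hiodon_rh1_1,Osteo_rh1),(Clupeo_rh1_A,Clupeo_rh1_B))));",
  C1 = "((Elops_dso,((Hiodon_rh1_1,Osteo_rh1),Clupeo_rh1_A)),(Elops_fwo,(Hiodon_rh1_2,Clupeo_rh1_B)));",
  C2 = "((Elops_dso,((Hiodon_rh1_1,Osteo_rh1),Clupeo_rh1_B)),(Elops_fwo,(Hiodon_rh1_2,Clupeo_rh1_A)));",
  C3 = "((Elops_dso,(Hiodon_rh1_2,Clupeo_rh1_A)),(Elops_fwo,((Hiodon_rh1_1,Osteo_rh1),Clupeo_rh1_B)));",
  C4 = "((Elops_dso,(Hiodon_rh1_2,Clupeo_rh1_B)),(Elops_fwo,((Hiodon_rh1_1,Osteo_rh1),Clupeo_rh1_A)));"
)

# Species-tree branches carrying the duplication(s) of each scenario, and the
# gene losses each scenario implies (copy absences drawn into the scenario,
# i.e. part of its definition, not user input).
.scenario_dup_branches <- list(
  A1 = c("Elopomorpha", "Osteoglossomorpha", "Clupeocephala"),
  A2 = c("Teleostei", "Osteoglossomorpha", "Clupeocephala"),
  B1 = c("Elopomorpha", "OsteoClupeo"),
  B2 = c("Elopomorpha", "OsteoClupeo"),
  B3 = c("Teleostei", "OsteoClupeo"),
  B4 = c("Teleostei", "OsteoClupeo"),
  B5 = c("Teleostei", "Clupeocephala"),
  B6 = c("Teleostei", "Clupeocephala"),
  C1 = "Teleostei", C2 = "Teleostei", C3 = "Teleostei", C4 = "Teleostei"
)

.scenario_implied_losses <- list(
  A1 = "Osteoglossomorpha_other",
  A2 = c("OsteoClupeo", "Osteoglossomorpha_other"),
  B1 = "Osteoglossomorpha_other",
  B2 = "Osteoglossomorpha_other",
  B3 = c("OsteoClupeo", "Osteoglossomorpha_other"),
  B4 = c("OsteoClupeo", "Osteoglossomorpha_other"),
  B5 = c("Osteoglossomorpha_other", "Clupeocephala"),
  B6 = c("Osteoglossomorpha_other", "Clupeocephala"),
  C1 = "Osteoglossomorpha_other", C2 = "Osteoglossomorpha_other",
  C3 = "Osteoglossomorpha_other", C4 = "Osteoglossomorpha_other"
)

#' Lineage-level gene-family topology of a scenario
#'
#' @param scenario_id One of [scenario_ids()].
#' @return Rooted `phylo` over the seven [lineage_tags()].
#' @export
lineage_topology <- function(scenario_id) {
  if (!scenario_id %in% names(.scenario_newick)) {
    stop("unknown scenario id: ", scenario_id)
  }
  ape::read.tree(text = .scenario_newick[[scenario_id]])
}

#' Packaged species trees
#'
#' `"compact"` is a five-tip lineage-level tree (one representative per major
#' teleost lineage plus an outgroup) used for desk-scale simulation and
#' hypothesis evaluation. `"full"` is a 24-taxon jawed-vertebrate tree with
#' denser elopomorph sampling. Branch lengths are in expected substitutions
#' per site, on the order observed for rod opsin coding sequence.
#'
#' @param which `"compact"` or `"full"`.
#' @return A rooted `phylo`.
#' @export
rh1_species_tree <- function(which = c("compact", "full")) {
  which <- match.arg(which)
  if (which == "compact") {
    return(ape::read.tree(text = paste0(
      "(Outgroup:0.45,(Elops:0.28,((Hiodon:0.14,Osteo:0.14):0.06,",
      "Clupeo:0.20):0.08):0.10);")))
  }
  ape::read.tree(system.file("extdata", "teleost_species_tree.nwk",
                             package = "rhodup", mustWork = TRUE))
}

#' Species group membership for a packaged species tree
#'
#' @param which `"compact"` or `"full"`.
#' @return Named list with elements `outgroup`, `elopomorpha`, `hiodon`,
#'   `osteoglossomorpha_other`, `clupeocephala` (character vectors of tip
#'   labels).
#' @export
rh1_species_groups <- function(which = c("compact", "full")) {
  which <- match.arg(which)
  if (which == "compact") {
    return(list(outgroup = "Outgroup", elopomorpha = "Elops",
                hiodon = "Hiodon", osteoglossomorpha_other = "Osteo",
                clupeocephala = "Clupeo"))
  }
  df <- read.delim(system.file("extdata", "teleost_species_groups.tsv",
                               package = "rhodup", mustWork = TRUE))
  split(df$species, df$group)[c("outgroup", "elopomorpha", "hiodon",
                                "osteoglossomorpha_other", "clupeocephala")]
}

# Species set of each lineage tag, given the group membership.
tag_species_sets <- function(groups) {
  list(Elops_dso = groups$elopomorpha,
       Elops_fwo = groups$elopomorpha,
       Hiodon_rh1_1 = groups$hiodon,
       Hiodon_rh1_2 = groups$hiodon,
       Osteo_rh1 = groups$osteoglossomorpha_other,
       Clupeo_rh1_A = groups$clupeocephala,
       Clupeo_rh1_B = groups$clupeocephala)
}

# Human-readable name for the species-tree clade below a branch.
clade_name <- function(tips, groups) {
  named <- list(
    Outgroup = groups$outgroup,
    Elopomorpha = groups$elopomorpha,
    Hiodon = groups$hiodon,
    Osteoglossomorpha_other = groups$osteoglossomorpha_other,
    Clupeocephala = groups$clupeocephala,
    Osteoglossomorpha = c(groups$hiodon, groups$osteoglossomorpha_other),
    OsteoClupeo = c(groups$hiodon, groups$osteoglossomorpha_other,
                    groups$clupeocephala),
    Teleostei = c(groups$elopomorpha, groups$hiodon,
                  groups$osteoglossomorpha_other, groups$clupeocephala))
  for (nm in names(named)) {
    if (setequal(tips, named[[nm]])) return(nm)
  }
  if (length(tips) == 1L) return(tips)
  paste(sort(tips), collapse = "+")
}

# Tip set of the named clade (inverse of clade_name for the named clades).
clade_tips <- function(name, groups) {
  named <- list(
    Outgroup = groups$outgroup,
    Elopomorpha = groups$elopomorpha,
    Hiodon = groups$hiodon,
    Osteoglossomorpha_other = groups$osteoglossomorpha_other,
    Clupeocephala = groups$clupeocephala,
    Osteoglossomorpha = c(groups$hiodon, groups$osteoglossomorpha_other),
    OsteoClupeo = c(groups$hiodon, groups$osteoglossomorpha_other,
                    groups$clupeocephala),
    Teleostei = c(groups$elopomorpha, groups$hiodon,
                  groups$osteoglossomorpha_other, groups$clupeocephala))
  if (name %in% names(named)) return(named[[name]])
  name
}
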