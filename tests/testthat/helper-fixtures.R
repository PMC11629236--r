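# Fixtures are generated in code at test time; nothing binary is stored.

# three-reaction ModelSEED-dialect TSV (one reversible)
write_toy_modelseed_tsv <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c(
    "id\tstoichiometry\treversibility",
    "rxn00001\t-1:cpd00001:c;-2:cpd00002:c;1:cpd00003:c\t>",
    "rxn00002\t-1:cpd00003:c;1:cpd00004:c\t=",
    "rxn00003\t-1:cpd00004:c;1:cpd00005:c\t<"), path)
  path
}

# BiGG-dialect JSON of the same network shape
write_toy_bigg_json <- function(path = tempfile(fileext = ".json")) {
  jsonlite::write_json(list(
    id = "toy_universal",
    reactions = list(
      list(id = "RXA", metabolites = list(A_c = -1, B_c = 1),
           lower_bound = 0, upper_bound = 1000),
      list(id = "RXB", metabolites = list(B_c = -1, C_c = 1),
           lower_bound = -1000, upper_bound = 1000)),
    metabolites = list(list(id = "A_c", compartment = "c"),
                       list(id = "B_c", compartment = "c"),
                       list(id = "C_c", compartment = "c"))),
    path, auto_unbox = TRUE, digits = NA)
  path
}

# four-reaction SBML L3 toy with a bio1 biomass reaction
write_toy_sbml <- function(path = tempfile(fileext = ".xml"),
                           biomass_id = "bio1") {
  writeLines(sprintf('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
  <model id="toy_sbml">
    <listOfSpecies>
      <species id="A_e" compartment="e"/>
      <species id="A_c" compartment="c"/>
      <species id="B_c" compartment="c"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="EX_A" reversible="true">
        <listOfReactants>
          <speciesReference species="A_e" stoichiometry="1"/>
        </listOfReactants>
      </reaction>
      <reaction id="T_A" reversible="false">
        <listOfReactants>
          <speciesReference species="A_e" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="A_c" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="CONV" reversible="false">
        <listOfReactants>
          <speciesReference species="A_c" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B_c" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="%s" reversible="false">
        <listOfReactants>
          <speciesReference species="B_c" stoichiometry="1"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>', biomass_id), path)
  path
}

# genome metadata table for selection / splitting tests
toy_records <- function() {
  data.frame(
    genome_id = sprintf("g%02d", 1:10),
    species = c("s1", "s1", "s2", "s2", "s3", "s4", "s5", "s6", "s7", "s8"),
    genus = rep(c("A", "B", "C"), c(4, 3, 3)),
    completeness = c(95, 99, 90, 90, 98, 97, 85, 92, 91, 96),
    contamination = c(1, 3, 0, 0, 0.5, 1, 2, 0, 1, 0),
    coarse_consistency = c(98, 91, 98, 91, 95, 90, 88, 93, 92, 94),
    stringsAsFactors = FALSE)
}

# miniature world shared by several suites (fast to generate)
tiny_world_config <- function(seed = 3L) {
  synthetic_world_config(n_reactions = 60, n_core = 20, n_modules = 4,
                         module_size = 4, n_clades = 2,
                         genomes_per_clade = 10, seed = seed)
}
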