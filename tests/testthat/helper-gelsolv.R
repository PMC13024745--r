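# Shared fixture builders (all fixtures are constructed in code)

fixture_path <- function(name) system.file("extdata", name, package = "gelsolv")

sul_composition <- function() read_composition(fixture_path("sulindac_groups.csv"))
meg_composition <- function() read_composition(fixture_path("meglumine_groups.csv"))

# A tiny custom group table written to a temp CSV
write_group_table <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Exact A_L dataset on a grid: S = S0 + slope * L
linear_dataset <- function(slope = 0.5, S0 = 1.0, grid = 1:6) {
  phase_solubility_dataset(grid, S0 + slope * grid, intrinsic_solubility = S0)
}
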