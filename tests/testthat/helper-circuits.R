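# Shared fixtures: tiny circuits and cheap configs, built in code.

toggle_topo <- function() {
  circuit_topology(tibble::tibble(
    source = c("A", "B"), target = c("B", "A"), type = c(2L, 2L)
  ))
}

# toggle switch plus a slaved reporter gene with no outgoing edges
toggle_reporter_topo <- function() {
  circuit_topology(tibble::tibble(
    source = c("A", "B", "A"),
    target = c("B", "A", "C"),
    type   = c(2L, 2L, 1L)
  ))
}

# symmetric strongly-bistable toggle parameters: G=50, k=0.5, B0=10, n=4,
# lambda=0.01 both ways
symmetric_toggle_params <- function() {
  c(Prod_of_A = 50, Deg_of_A = 0.5, Prod_of_B = 50, Deg_of_B = 0.5,
    Trd_of_AToB = 10, Num_of_AToB = 4, Fld_of_AToB = 0.01,
    Trd_of_BToA = 10, Num_of_BToA = 4, Fld_of_BToA = 0.01)
}

# single unregulated gene: one self-less "circuit" needs an edge, so use a
# regulator R driving a target T; R itself is unregulated
single_link_topo <- function(type = 2L) {
  circuit_topology(tibble::tibble(source = "R", target = "T", type = type))
}

quick_ranges <- function(topo, seed = 42, mc_samples = 2000) {
  set.seed(seed)
  build_parameter_ranges(topo, mc_samples = mc_samples)
}
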