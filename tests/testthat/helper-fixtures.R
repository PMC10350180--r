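# Small builders used across the test files.

make_nodes <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  names(df) <- c("node_id", "x", "y", "z", "parent_id", "structure",
                 "parcel_id")[seq_along(df)]
  df
}

# a soma with one straight axonal chain through the given parcels
chain_neuron <- function(id, parcels, soma_xyz = c(0, 0, 0), step = 10,
                         soma_parcel = "SRC") {
  n <- length(parcels)
  nodes <- data.frame(
    node_id = seq_len(n + 1L),
    x = soma_xyz[1L] + step * (0:n),
    y = soma_xyz[2L], z = soma_xyz[3L],
    parent_id = c(NA, seq_len(n)),
    structure = c("soma", rep("axon", n)),
    parcel_id = c(soma_parcel, parcels),
    stringsAsFactors = FALSE
  )
  neuron_reconstruction(id, nodes)
}

random_count_matrix <- function(n = 8, k = 5, max_count = 20) {
  m <- matrix(sample(0:max_count, n * k, replace = TRUE), n, k,
              dimnames = list(paste0("n", seq_len(n)),
                              paste0("r", seq_len(k))))
  m[rowSums(m) == 0, 1L] <- 1
  m
}

unit_cube <- function() {
  m <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  dimnames(m) <- NULL
  m
}

# 27-point lattice on the unit cube (dense enough that no lattice point
# dominates the hull volume on its own)
cube_lattice <- function() {
  m <- as.matrix(expand.grid(c(0, 0.5, 1), c(0, 0.5, 1), c(0, 0.5, 1)))
  dimnames(m) <- NULL
  m
}

extdata <- function(name) {
  path <- system.file("extdata", name, package = "axonclass")
  if (path == "") path <- file.path("../../inst/extdata", name)
  path
}
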