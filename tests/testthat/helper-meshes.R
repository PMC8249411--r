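# Expensive meshes are built once per test run and shared across files.
.mesh_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .mesh_cache)) assign(key, builder(), envir = .mesh_cache)
  get(key, envir = .mesh_cache)
}

rbc_surface <- function() cached("surf", function() implicit_rbc(rbc_geometry()))

rbc_mesh <- function(target_edges) {
  cached(paste0("rbc_", target_edges), function()
    mesh_implicit(rbc_surface(), target_edges = target_edges))
}

# full-scale relaxed mesh, with wall-clock time recorded
rbc_mesh_full <- function() {
  cached("rbc_full", function() {
    t0 <- Sys.time()
    m <- mesh_implicit(rbc_surface(), target_edges = 121000)
    attr(m, "elapsed_s") <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    m
  })
}

strained_surface <- function(theta, xi) {
  deform_surface(rbc_surface(), affine_deformation(theta, xi))
}

strained_mesh_full <- function(theta, xi) {
  cached(sprintf("strained_%g_%g", theta, xi), function()
    mesh_implicit(strained_surface(theta, xi), target_edges = 121000))
}

sphere_mesh <- function() {
  cached("sphere", function()
    mesh_implicit(implicit_sphere(1), target_edges = 2000))
}

sweep_12k <- function() {
  cached("sweep12k", function()
    strain_sweep(rbc_geometry(), target_edges = 12000))
}
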