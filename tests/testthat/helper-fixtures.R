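# Small phantoms and cached simulation results shared across test files.
# Everything is generated in code; the cache only avoids recomputing the
# same deterministic objects.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# phantom spec scaled down to a 32 mm-voxel-budget grid for fast tests
small_spec <- function(shape = c(48, 48, 6), seed = 1,
                       body_semiaxes = c(120, 85),
                       bone_outer_mm = c(16, 24), bone_shell_mm = c(4, 8),
                       n_bone_lesions = 1, n_soft_lesions = 1, ...) {
  phantom_spec(shape = shape, spacing = c(6, 6, 6),
               body_semiaxes = body_semiaxes, n_bones = 2,
               bone_outer_mm = bone_outer_mm, bone_shell_mm = bone_shell_mm,
               bone_jitter_mm = 6, n_bone_lesions = n_bone_lesions,
               n_soft_lesions = n_soft_lesions, seed = seed, ...)
}

# one small phantom with mu-maps and a noiseless PET pair, computed once
small_case <- function() {
  cached("small_case", {
    ph <- generate_phantom(small_spec(seed = 7))
    mm <- phantom_mumaps(ph)
    cfg <- recon_config()
    pets <- simulate_pet_pair(ph, mm$mu4c, mm$muref, cfg)
    cmap <- compute_correction_map(pets$pet_4c, pets$pet_ctmr, ph$pelvic_mask)
    list(phantom = ph, mu4c = mm$mu4c, muref = mm$muref, ct_lac = mm$ct_lac,
         pets = pets, cmap = cmap, cfg = cfg)
  })
}

random_volume <- function(d = c(8, 8, 4), lo = 500, hi = 5000, seed = 1,
                          role = "activity_bqml") {
  set.seed(seed)
  image_volume(array(runif(prod(d), lo, hi), d), spacing = c(2, 2, 2),
               role = role)
}
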