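# Hand-constructed scalar models and small data generators used across tests.

# scalar linear model in internal units (no scaling): A' = a, K = k,
# C_y = cy, C_z = cz
scalar_model <- function(a, k, cy, cz) {
  spec <- dpad_spec(n_y = 1, n_z = 1, n_x = 1, n_1 = 1)
  m <- build_model(spec)
  m$sec1$A$W <- matrix(a)
  m$sec1$K$W <- matrix(k)
  m$sec1$read$W <- matrix(cz)
  m$Cy1$W <- matrix(cy)
  m
}

# multivariate linear model with given matrices, single section
matrix_model <- function(A, K, Cy, Cz) {
  spec <- dpad_spec(n_y = ncol(K), n_z = nrow(Cz), n_x = nrow(A),
                    n_1 = nrow(A))
  m <- build_model(spec)
  m$sec1$A$W <- A
  m$sec1$K$W <- K
  m$sec1$read$W <- Cz
  m$Cy1$W <- Cy
  m
}

# small, quickly learnable linear world for smoke fits
quick_world <- function(seed = 3, Tn = 1500, n_y = 3, n_z = 2) {
  set.seed(seed)
  mdl <- random_linear_model(n_x = 4, n_1 = 2, n_y = n_y, n_z = n_z)
  generate_data(mdl, Tn)
}

quick_cfg <- function(max_epochs = 25, lr = 0.01, ...) {
  fit_config(max_epochs = max_epochs, patience = 3, lr = lr,
             batch_size = 8, seed = 11, ...)
}

# cheap content fingerprint used by leakage tests
digest_series <- function(x) {
  v <- as.vector(x)
  c(sum(v), sum(v^2), sum(v * seq_along(v)))
}
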