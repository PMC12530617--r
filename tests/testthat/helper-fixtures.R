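# Shared fixtures built in code. The vocabulary/schedule pair is the one
# most tests run against; heavier trained models are built lazily once per
# session by the helpers below and cached in this environment.

.test_cache <- new.env(parent = emptyenv())

test_vocab <- function() {
  if (is.null(.test_cache$vocab)) {
    .test_cache$vocab <- build_vocabulary(c("CCO", "CC(=O)[O-]", "c1ccccc1N"))
  }
  .test_cache$vocab
}

test_schedule <- function(T_steps = 10, vocab = test_vocab(), ...) {
  make_schedule(T_steps, channel_K(vocab), ...)
}

tiny_config <- function(...) {
  denoiser_config(layers = 2, hidden = 16, heads = 2, dropout = 0,
                  rni_dim = 4, time_embed_dim = 8, ...)
}

tiny_model <- function(vocab, schedule, n, seed = 1, ...) {
  set.seed(seed)
  conf <- tiny_config(...)
  structure(list(params = init_denoiser(conf, vocab), config = conf,
                 vocab = vocab, schedule = schedule, n = as.integer(n)),
            class = "moldiff_model")
}

# random valid schedule for property sweeps (single shared channel width)
random_schedule <- function(K, T_steps) {
  make_schedule(T_steps, c(A = K, C = K, E = K),
                mask_fraction_final = stats::runif(1, 0.5, 1),
                uniform_weight = stats::runif(1, 0, 0.3))
}

# brute-force posterior by Bayes enumeration over x_{t-1}
oracle_posterior <- function(x_t, x0, t, channel, schedule) {
  Qt <- transition_matrix(t, channel, schedule)
  Qprev <- cumulative_matrix(t - 1, channel, schedule)
  v <- Qt[x_t, ] * Qprev[, x0]
  if (sum(v) == 0) return(v)
  v / sum(v)
}

# the chain fixture used by the training-based tests (8 molecules)
chain_fixture <- function() {
  if (is.null(.test_cache$chain_fx)) {
    .test_cache$chain_fx <- make_fixture(
      fixture_spec("enumerated_chains", max_heavy_atoms = 4,
                   elements = c("C", "O"), max_heteroatoms = 1,
                   n_molecules = 64, seed = 1))
  }
  .test_cache$chain_fx
}

# overfit model on a single molecule (500 optimization steps); cached for
# reuse across tests
single_molecule_model <- function() {
  if (is.null(.test_cache$single_model)) {
    cfg <- desk_train_config(T_steps = 50, epochs = 500, batch_size = 48,
                             seed = 3)
    .test_cache$single_model <- train_model(rep("CCO", 48), cfg)
  }
  .test_cache$single_model
}

# distribution model on the 8-molecule chain fixture (1000 steps); cached
chain_model <- function() {
  if (is.null(.test_cache$chain_model)) {
    fx <- chain_fixture()
    cfg <- desk_train_config(T_steps = 24, epochs = 500, batch_size = 32,
                             seed = 5)
    .test_cache$chain_model <- train_model(fx$corpus, cfg)
  }
  .test_cache$chain_model
}

# conditional (logP) model on the chain fixture; cached
conditional_chain_model <- function() {
  if (is.null(.test_cache$cond_model)) {
    fx <- chain_fixture()
    props <- fx$properties[match(fx$corpus, fx$properties$smiles), ]
    cfg <- desk_train_config(T_steps = 24, epochs = 300, batch_size = 32,
                             seed = 5, condition_on = "logp")
    .test_cache$cond_model <- train_model(fx$corpus, cfg, properties = props)
  }
  .test_cache$cond_model
}
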