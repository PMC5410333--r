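# Shared synthetic classification task: two well-separated Gaussian
# classes, used to sanity-check both classifiers.
make_gaussian_task <- function(n_train = 100, n_test = 50, sep = 5,
                               d = 2, seed = 1) {
  withr::with_seed(seed, {
    tr <- rbind(matrix(rnorm(n_train * d), n_train, d),
                matrix(rnorm(n_train * d, mean = sep), n_train, d))
    te <- rbind(matrix(rnorm(n_test * d), n_test, d),
                matrix(rnorm(n_test * d, mean = sep), n_test, d))
    list(train_x = tr, train_y = rep(1:2, each = n_train),
         test_x = te, test_y = rep(1:2, each = n_test))
  })
}
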