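# Memoised heavyweight training runs shared by the acceptance and
# staged-protocol tests (testthat runs all files in one process).

acc_env <- new.env()

joint_run <- function() {
  if (is.null(acc_env$joint)) {
    split <- benchmark_split(n_train = 200L, n_test = 40L, size = 64L,
                             n_classes = 3L, seed = 0L)
    cfg <- benchmark_train_config(64L, epochs = 40L, seed = 0L)
    st <- train_joint(split$train, cfg,
                      camseg_config(n_classes = 3L, seed = 0L))
    acc_env$joint <- list(state = st, split = split,
                          eval = evaluate_model(st, split$test))
  }
  acc_env$joint
}

ablation_runs <- function() {
  if (is.null(acc_env$ablation)) {
    # reduced-schedule grid on a 96-patch benchmark: classifier stages 30
    # epochs, standalone stages 12, joint 40; one fixed seed
    split <- benchmark_split(n_train = 96L, n_test = 24L, size = 64L,
                             n_classes = 3L, seed = 0L)
    out <- list(split = split)
    # vanilla CAM chain
    out$cam <- run_benchmark("cls_cam", split, epochs = 30L,
                             epochs_standalone = 12L, seed = 0L)
    # the DA classifier stage is shared between the no-CRF and CRF chains
    cfg_cls <- benchmark_train_config(64L, epochs = 30L, seed = 0L)
    st_cls <- train_classifier(split$train, cfg_cls,
                               camseg_config(n_classes = 3L, seed = 0L))
    out$cls_state <- st_cls
    for (use_crf in c(FALSE, TRUE)) {
      st1 <- st_cls
      st1$train_config$use_crf <- use_crf
      pd <- camseg:::pseudo_dataset(st1, split$train)
      st2 <- train_standalone(
        pd, cfg = benchmark_train_config(64L, epochs = 12L, seed = 1L),
        model_config = camseg_config(n_classes = 3L, seed = 1L))
      ev <- evaluate_model(st2, split$test)
      out[[if (use_crf) "da_crf" else "da"]] <- list(miou = ev$miou, eval = ev)
    }
    out$joint <- run_benchmark("joint", split, epochs = 40L, seed = 0L)
    acc_env$ablation <- out
  }
  acc_env$ablation
}

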