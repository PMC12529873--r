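#!/usr/bin/env Rscript
# Step 2 — train the three study arms.
#
# Trains, at desk scale (48 px images, 1-stack 16-channel hourglass):
#   centralized  - one model on the pooled training split,
#   local        - one model per hospital on its own data,
#   fedavg       - FedAvg, 5 local epochs x 6 rounds.
# Saves checkpoints and training histories under results/arms/. Expect a few
# minutes of CPU time.

suppressPackageStartupMessages(library(fedspine))

seed <- 1L
out <- "results/arms"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

st <- run_desk_study(seed = seed)
saveRDS(st, file.path(out, "study.rds"))

save_checkpoint(st$fits$centralized$best_params, st$config,
                list(arm = "centralized"), file.path(out, "centralized.ckpt"))
for (cid in names(st$fits$locals))
  save_checkpoint(st$fits$locals[[cid]]$best_params, st$config,
                  list(arm = paste0("local:", cid)),
                  file.path(out, paste0("local_", cid, ".ckpt")))
save_checkpoint(st$fits$fedavg$best_params, st$config, list(arm = "fedavg"),
                file.path(out, "fedavg.ckpt"))

utils::write.csv(st$fits$centralized$history,
                 file.path(out, "centralized_history.csv"), row.names = FALSE)
write_fl_history(st$fits$fedavg$history, file.path(out, "fedavg_history.csv"))

cat(sprintf("centralized: stopped at epoch %d, best val %.2f mm\n",
            st$fits$centralized$stopped_epoch,
            st$fits$centralized$best_val_metric))
for (cid in names(st$fits$locals))
  cat(sprintf("local %s: stopped at epoch %d, best val %.2f mm\n", cid,
              st$fits$locals[[cid]]$stopped_epoch,
              st$fits$locals[[cid]]$best_val_metric))
cat(sprintf("fedavg: best round %d, best pooled val %.2f mm\n",
            st$fits$fedavg$best_round, st$fits$fedavg$best_val_metric))
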