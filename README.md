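# limbid

Upper-limb bioimpedance features for wearable identity recognition.

## The problem

Bioelectrical impedance spectra carry enough anatomical information to
distinguish people, but readings taken at the fingers are notoriously
irreproducible: finger impedance drifts with hand temperature,
day-to-day physiology (hydration, blood flow, vasomotion) and the exact
placement of the finger on the electrode. `limbid` implements and
evaluates a feature-engineering answer for a five-electrode wrist
wearable (wrist electrode `e0`, finger electrodes `e1`–`e4`, impedance
magnitude of all 10 electrode pairs over 20–500 kHz in 20 kHz steps).

The electrical paths compose additively — a wrist–finger channel reads
`Z_limb + Z_fi`, a finger–finger channel reads `Z_fi + Z_fj` — so the
**pure upper-limb impedance** can be recovered from any triple
`(e0, ei, ej)`:

    Z_limb = ( Z(0,i) + Z(0,j) - Z(i,j) ) / 2

Both finger impedances, and any artifact multiplying a single finger,
cancel exactly. Six such triples exist, giving a 6 x 25 feature set that
is temperature-, placement- and drift-robust. Alongside it the package
builds **ratiometric features** (six canonical same-frequency ratios of
finger-pair channels, invariant to drift common to all fingers) and the
**raw finger-pair** spectra, and evaluates closed-set and open-set
identification under date-stratified cross-validation with five
classifiers (random forest, regularised LDA, 1-NN, polynomial SVM, and a
compact 1D CNN implemented in base R).

The reference dataset behind the method is not publicly deposited, so the
package ships a seeded synthetic generator (single-dispersion Cole
tissue spectra plus day-drift, temperature, placement and device-noise
models) that reproduces the statistical structure the analysis depends
on; it also reads user-supplied long-format CSVs of real channel
measurements in the same schema (see `?read_study_csv`).

## Worked example

```r
library(limbid)

# a hard synthetic study: strong finger drift + placement jitter
st <- simulate_study(n_subjects = 8, n_days = 3, repeats_per_day = 6,
                     config = study_config(sigma_day_finger = 0.10,
                                           sigma_day_finger_idio = 0.04,
                                           placement_jitter = c(0.90, 1.12)),
                     seed = 42)

cv_limb   <- daily_cv_profile(st, "limb")
cv_finger <- daily_cv_profile(st, "finger")
cat(sprintf("mean day-to-day CV: limb %.4f, raw finger %.4f\n",
            mean(cv_limb$cv_mean), mean(cv_finger$cv_mean)))
rf <- classifier_spec("rf", seed = 42)
for (fam in c("finger", "ratio", "limb", "ratio+limb"))
  cat(sprintf("RF day-fold accuracy [%-10s] %6.2f %%\n", fam,
              cross_validated_accuracy(st, fam, rf)))
rep <- evaluate_study(st, "ratio+limb", rf)
cat(sprintf("open-set: EER %.2f %%, AUC %.4f\n", rep$eer, rep$auc))
```

Output:

```
mean day-to-day CV: limb 0.0052, raw finger 0.1022
RF day-fold accuracy [finger    ]  74.31 %
RF day-fold accuracy [ratio     ]  97.92 %
RF day-fold accuracy [limb      ] 100.00 %
RF day-fold accuracy [ratio+limb] 100.00 %
open-set: EER 0.00 %, AUC 1.0000
```

Reading it: raw finger spectra drift ~20x more day to day than the
extracted limb spectra (CV 0.10 vs 0.005), and a day-fold-validated
random forest misidentifies a quarter of sessions from raw finger
channels while the limb features — algebraically immune to the injected
placement jitter and most of the drift — identify everyone. The open-set
report sweeps an acceptance threshold over the pooled posteriors: EER is
the operating point where false acceptances equal false rejections, AUC
the area under the resulting ROC curve.

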