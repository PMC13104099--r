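# Default calibration of the synthetic corpus generator (version 1).
#
# Domain-level truth probabilities are conditional on a trial reaching the
# domain (the hierarchical screen truncates at the first exclusion or
# non-RCT flag). They reproduce the observed per-domain frequencies of a
# 206-trial COVID-19 trial corpus screened with the six-domain integrity
# tool: e.g. domain-2 exclusion 51/198, domain-3 awaiting 62/137.
# author_response gives the probability that an awaiting verdict in that
# domain is resolved to no-concern after author correspondence
# (reclassification tallies, e.g. 17/62 in the ethics domain).
version: 1
n_reviews: 23
trials_per_review:
  dist: nbinom
  mu: 9.0
  size: 2.5
  min: 2
arm_size:
  dist: lognormal
  meanlog: 4.38   # per-arm; trial totals then have median ~160
  sdlog: 1.0
  min: 10
control_risk: 0.2
true_log_effect: 0.0
issue_prevalence:
  domain1: {exclude: 0.0388, awaiting: 0.0097, non_rct: 0.0}
  domain2: {exclude: 0.2576, awaiting: 0.1414, non_rct: 0.0505}
  domain3: {exclude: 0.0, awaiting: 0.4526, non_rct: 0.0}
  domain4: {exclude: 0.0, awaiting: 0.0584, non_rct: 0.0}
  domain5: {exclude: 0.0, awaiting: 0.2044, non_rct: 0.0073}
  domain6: {exclude: 0.0, awaiting: 0.2059, non_rct: 0.0}
author_response:
  domain1: 0.0
  domain2: 0.25
  domain3: 0.274
  domain4: 0.0
  domain5: 0.036
  domain6: 0.107
assessor_profiles:
  # 3x3 row-stochastic confusion matrices, P(rated | true), rows and
  # columns ordered no_concern < awaiting < exclude. Beginners shift mass
  # from no_concern toward awaiting (over-flagging); seniors are taken as
  # the reference standard.
  beginner:
    - [0.70, 0.25, 0.05]
    - [0.10, 0.80, 0.10]
    - [0.05, 0.15, 0.80]
  intermediate:
    - [0.85, 0.12, 0.03]
    - [0.15, 0.75, 0.10]
    - [0.03, 0.07, 0.90]
  senior:
    - [1.0, 0.0, 0.0]
    - [0.0, 1.0, 0.0]
    - [0.0, 0.0, 1.0]
rob_distribution: {low: 0.333, some_concerns: 0.447, high: 0.220}
time_model:
  # mean seconds per study per domain; lognormal draws with sdlog below
  beginner: [82, 152, 259, 207, 363, 555]
  intermediate: [65, 123, 229, 200, 216, 419]
  senior: [65, 123, 229, 200, 216, 419]
  sdlog: 0.5
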