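# Base-case parameterization of the AI-aided LVO detection model.
# Flat keys; omitted keys take these same defaults. Probabilities are
# fractions (0-1); costs are 2019 USD.

# clinical
p_lvo: 0.306          # LVO prevalence among CTA-receiving suspected strokes
p_eligible: 0.438     # IAT-eligible fraction of LVO patients
p_missed: 0.06        # LVOs missed under standard care
reduction: 0.50       # fraction of misses recovered by the AI aid
p_recurrent: 0.0284   # annual recurrent-stroke probability
age0: 66
cohort_n: 71840
mrs_iat: [0.11, 0.18, 0.20, 0.17, 0.16, 0.04, 0.14]      # mRS 0-5, death
mrs_no_iat: [0.05, 0.08, 0.11, 0.17, 0.27, 0.12, 0.20]

# costs (USD 2019)
acute_by_state: [4350, 5117, 5885, 22695, 30704, 36468, 4603]  # mRS 0-6, <90d
longterm_by_state: [3936, 4631, 5325, 18944, 25631, 41621]     # mRS 0-5, /yr
tx_iat: 11728
tx_no_iat: 1004
ai_per_analysis: 40
discount_costs: 0.04
fp_cost_per_point: 0

# utilities
utility_by_state: [0.95, 0.93, 0.83, 0.62, 0.42, 0.11]
discount_utilities: 0.015

# analysis settings
cycles: 70
wtp_per_qaly: 25662
acute_year_fraction: 0.2464066   # 90 / 365.25
non_lvo_profile: healthy
recurrence_rule: clamp_max
recurrence_acute_costs: false
fp_rate_points: 0
seed: 1
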