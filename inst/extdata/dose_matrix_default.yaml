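# Default starting physical-activity doses by obesity level x activity status.
# Placeholder values satisfying the clinical ordering constraint that severely
# obese, inactive patients start with shorter durations and no more frequent
# sessions than overweight, inactive patients. Fully overridable via a config
# file with this schema; the ordering constraint is re-checked at load time.
# minutes: minutes per session; sessions: sessions per week.
overweight:
  inactive:          {minutes: 30, sessions: 3, intensity: moderate}
  somewhat_active:   {minutes: 35, sessions: 4, intensity: moderate}
  moderately_active: {minutes: 40, sessions: 4, intensity: moderate}
  active:            {minutes: 45, sessions: 5, intensity: moderate}
obese:
  inactive:          {minutes: 25, sessions: 3, intensity: moderate}
  somewhat_active:   {minutes: 30, sessions: 3, intensity: moderate}
  moderately_active: {minutes: 35, sessions: 4, intensity: moderate}
  active:            {minutes: 40, sessions: 5, intensity: moderate}
severe_obese:
  inactive:          {minutes: 20, sessions: 3, intensity: light}
  somewhat_active:   {minutes: 25, sessions: 3, intensity: moderate}
  moderately_active: {minutes: 30, sessions: 4, intensity: moderate}
  active:            {minutes: 35, sessions: 4, intensity: moderate}
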