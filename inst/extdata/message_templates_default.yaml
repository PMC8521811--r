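# Check-in message templates by tone class. Bodies use {placeholder}
# substitution and must pass the autonomy-supportive language lint (no
# "should", "must", "have to", "need to"); templates are linted at load time.
- id: advance_1
  tone_class: advance
  body: >-
    Great work, {name}! You met your goals. If it feels right, you may try
    {new_goal} minutes of activity this week — {activity} could be a fun way
    to get there.
- id: advance_2
  tone_class: advance
  body: >-
    {name}, you are making real progress. You could aim for {new_goal}
    minutes this week if you feel ready.
- id: hold_1
  tone_class: hold
  body: >-
    Thanks for checking in, {name}. Keeping your goal at {new_goal} minutes
    this week may help it feel doable. {activity} could be a good fit.
- id: ease_1
  tone_class: ease
  body: >-
    {name}, some weeks are harder than others. You may find {new_goal}
    minutes more realistic this week — small steps still count.
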