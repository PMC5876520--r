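name: soccer_kick
phases:
  - phase: last_step
    start: LS1        # landing of a kicking leg
    performing: LS2   # last step of a kicking leg before impact
    end: LS3          # toe-off of a kicking leg
  - phase: backswing
    start: LS3
    performing: LS4   # backswing of a kicking leg
    end: LS5          # maximum hip extension
  - phase: acceleration
    start: LS5
    performing: LS6   # acceleration of a kicking leg
    end: LS7          # ball impact
  - phase: follow_through
    start: LS7
    performing: LS8   # follow-through
    end: LS9          # toe speed inflection
  - phase: landing
    start: LS9
    performing: LS10  # landing of a kicking leg
    end: LS11         # end of kicking
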