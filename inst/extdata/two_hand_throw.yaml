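name: two_hand_throw
phases:
  - phase: wind_up
    start: LT1        # ready
    performing: LT2   # bringing two hands behind
    end: LT3          # two hands behind of a head
  - phase: throw
    start: LT3
    performing: LT4   # arms forward
    end: LT5          # maximum arm stretch
  - phase: follow_through
    start: LT5
    performing: LT6   # follow-through
    end: LT7          # end of throwing
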