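by mouth
by oral route
please
with food
with water
with meals
with a meal
with or without food
on an empty stomach
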