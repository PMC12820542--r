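alias,canonical
perceived usefulness,performance expectancy
relative advantage,performance expectancy
perceived ease of use,effort expectancy
complexity,effort expectancy
severity,perceived severity
vulnerability,perceived vulnerability
price value,financial cost
intention to use,behavioral intention
use behavior,actual behavior
subjective norm,social influence
perceived behavioral control,self-efficacy
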