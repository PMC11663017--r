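category	text
Pattern	I saw geometric patterns.
Pattern	I saw kaleidoscopic patterns.
Pattern	I saw fractals.
Pattern	I saw patterns.
Pattern	I saw repetitions.
Movement	I saw things breathing.
Movement	I saw things morphing.
Movement	I saw things drifting.
Movement	I saw things waving.
Movement	I saw things melting.
Movement	I saw things flowing.
Movement	I saw tracers and trails.
Color	I saw colors.
Color	I saw colors changing.
Color	Colors were beautiful.
Color	I saw rainbows.
Color	I saw colors I had never seen before.
Entities	I saw entities.
Entities	I saw aliens.
Entities	I saw angels.
Entities	I saw demons.
Entities	I saw elves.
Entities	I saw God.
Global visual alterations	My vision was blurry.
Global visual alterations	My vision was sharpened.
Global visual alterations	Everything looked dark.
Global visual alterations	Everything looked bright.
Global visual alterations	I saw a bright light.
Distortion	Everything was distorted.
Distortion	I saw things in my peripheral vision.
Distortion	I saw a distorted face.
Distortion	I saw cartoons.
Distortion	I saw things get bigger.
Distortion	I saw things get smaller.
Distortion	I saw things change in size.
Affect	I saw beauty.
Affect	What I saw scared me.
Other	I experienced synesthesia.
Other	I saw a tunnel.
Other	I saw things when I closed my eyes.
Other	I could not tell what was real.
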