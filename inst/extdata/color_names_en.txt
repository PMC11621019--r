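# Common English color names excluded as responses in the association task.
red
orange
yellow
green
blue
purple
violet
pink
brown
black
white
grey
gray
cyan
magenta
turquoise
teal
maroon
navy
olive
beige
cream
gold
silver
bronze
indigo
lavender
lilac
crimson
scarlet
salmon
peach
coral
khaki
tan
burgundy
mauve
aqua
azure
mint
emerald
jade
ruby
amber
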