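the quick brown fox jumps over the lazy dog
my watch fell in the water
prevailing winds from the east
never too rich and never too thin
breathing is difficult today
i can see the rings on saturn
physics and chemistry are hard
there will be some fog tonight
this is a very good idea
you are a wonderful example
do not walk too quickly
a picture is worth many words
the cat sat on the warm mat
we went to the park on sunday
please bring me a glass of water
the weather is lovely this morning
she sells sea shells by the shore
time flies when you are having fun
a rolling stone gathers no moss
every cloud has a silver lining
practice makes perfect every day
the early bird catches the worm
actions speak louder than words
honesty is the best policy
the children played in the garden
music soothes the troubled mind
reading opens doors to new worlds
kindness costs nothing at all
the train leaves at nine sharp
dinner will be ready soon
remember to lock the front door
the library closes at five today
autumn leaves fall from the trees
a friend in need is a friend indeed
the coffee is too hot to drink
birds sing sweetly in the spring
keep your friends close to you
the mountain path was steep and long
write your name at the top
the answer is in the back of the book
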